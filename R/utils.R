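# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed_ <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Derive a child seed from a base seed and a stage label; stays below 2^31.
derive_seed_ <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587)
}

# Rank-based AUC of scores for a binary 0/1 label (Mann-Whitney).
auc_ <- function(scores, y) {
  y <- as.integer(y)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Mean of each f x f block of matrix m (trailing rows/cols dropped).
block_mean_ <- function(m, f) {
  nr <- nrow(m) %/% f
  nc <- ncol(m) %/% f
  if (nr == 0L || nc == 0L) stop("matrix smaller than one block")
  m <- m[seq_len(nr * f), seq_len(nc * f), drop = FALSE]
  # reduce rows then columns
  dim(m) <- c(f, nr, nc * f)
  m2 <- colMeans(m)                       # nr x (nc*f)
  dim(m2) <- c(nr, f, nc)
  m3 <- apply(m2, c(1L, 3L), mean)
  matrix(m3, nr, nc)
}

# Mean of each f x f block of squared values minus squared block mean -> variance.
block_sd_ <- function(m, f) {
  mu <- block_mean_(m, f)
  mu2 <- block_mean_(m * m, f)
  v <- pmax(mu2 - mu * mu, 0)
  sqrt(v)
}

# 2-D integral image; S[i+1, j+1] = sum of m[1:i, 1:j].
integral_image_ <- function(m) {
  S <- matrix(0, nrow(m) + 1L, ncol(m) + 1L)
  S[-1L, -1L] <- apply(apply(m, 2L, cumsum), 1L, cumsum) |> t()
  S
}

# Sum of m over rows r0..r1, cols c0..c1 (1-based inclusive) via integral image.
integral_sum_ <- function(S, r0, r1, c0, c1) {
  S[r1 + 1L, c1 + 1L] - S[r0, c1 + 1L] - S[r1 + 1L, c0] + S[r0, c0]
}

stopif_ <- function(cond, msg) if (cond) stop(msg, call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
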