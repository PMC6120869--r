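# Internal linear SVM with per-sample weights, plus calibration maps.
#
# The grade-by-class weighting scheme assigns different weights to samples
# of the same class (one weight per grade x class cell), which class-weight
# interfaces of off-the-shelf SVMs cannot express. The primal weighted
# squared-hinge objective
#   0.5 ||w||^2 + C * M * sum_i v_i xi_i^2 / sum_i v_i ,
#   xi_i = max(0, 1 - s_i (x_i.w + b)),  s_i in {-1, +1},
# is smooth and convex and is minimized with L-BFGS-B using analytic
# gradients; the result is deterministic. The data term is a weighted
# mean (times the fixed multiplier M), so the fit is invariant to
# duplicating the training set and C keeps its meaning at any n.

wlsvm_fit_ <- function(X, y, v = NULL, C = 1, maxit = 300L, M = 256) {
  n <- nrow(X); d <- ncol(X)
  stopifnot(length(y) == n)
  s <- 2 * as.numeric(y) - 1
  if (is.null(v)) v <- rep(1, n)
  v <- v / sum(v) * M
  obj <- function(theta) {
    w <- theta[seq_len(d)]; b <- theta[d + 1L]
    f <- drop(X %*% w) + b
    xi <- pmax(0, 1 - s * f)
    0.5 * sum(w * w) + C * sum(v * xi * xi)
  }
  grad <- function(theta) {
    w <- theta[seq_len(d)]; b <- theta[d + 1L]
    f <- drop(X %*% w) + b
    xi <- pmax(0, 1 - s * f)
    coefv <- -2 * C * v * s * xi
    c(w + drop(crossprod(X, coefv)), sum(coefv))
  }
  fit <- optim(rep(0, d + 1L), obj, grad, method = "L-BFGS-B",
               control = list(maxit = maxit, factr = 1e7))
  list(w = fit$par[seq_len(d)], b = fit$par[d + 1L], value = fit$value,
       convergence = fit$convergence)
}

wlsvm_score_ <- function(fit, X) drop(X %*% fit$w) + fit$b

# Isotonic (PAVA) calibration: piecewise-constant non-decreasing map from
# score to [0,1]. Ties in x are collapsed to their (non-decreasing) fitted
# value; out-of-range scores clamp to the nearest plateau.
isotonic_fit_ <- function(scores, y) {
  ord <- order(scores)
  iso <- isoreg(scores[ord], as.numeric(y)[ord])
  x <- iso$x; yf <- iso$yf
  ux <- unique(x)
  uy <- vapply(ux, function(v) max(yf[x == v]), numeric(1))
  uy <- cummax(uy)  # guard: collapse of ties must stay monotone
  structure(list(x = ux, y = pmin(pmax(uy, 0), 1)), class = "isotonic_map")
}

isotonic_predict_ <- function(map, s) {
  idx <- findInterval(s, map$x)
  idx[idx < 1L] <- 1L
  map$y[idx]
}

# Platt (sigmoid) calibration via logistic regression of labels on scores.
platt_fit_ <- function(scores, y) {
  fit <- suppressWarnings(glm(y ~ scores, family = binomial(),
                              data = data.frame(scores = scores, y = as.numeric(y))))
  cf <- coef(fit)
  if (any(!is.finite(cf))) cf <- c(0, 1)
  structure(list(a = unname(cf[1]), b = unname(cf[2])), class = "platt_map")
}

platt_predict_ <- function(map, s) plogis(map$a + map$b * s)

# Stratified fold assignment at the patient level: patients of each class
# are shuffled and dealt round-robin into n_folds groups.
stratified_folds_ <- function(y, n_folds, seed) {
  with_seed_(seed, {
    fold <- integer(length(y))
    for (cls in unique(y)) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    fold
  })
}
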