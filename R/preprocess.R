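# Stain/intensity normalization, tissue detection, and region tiling.

#' Built-in H&E stain reference profile
#'
#' Target appearance for stain normalization: conventional hematoxylin and
#' eosin optical-density vectors plus per-stain robust (99th percentile)
#' concentration maxima that normalized images are rescaled to.
#'
#' @param max_c Length-2 robust concentration maxima (hematoxylin, eosin).
#' @return A `stain_reference`: list with `id`, `S` (3 x 2 OD vector
#'   matrix), `max_c`.
#' @export
he_reference <- function(max_c = c(hematoxylin = 1.0, eosin = 0.8)) {
  structure(list(id = "builtin-he", S = he_stain_vectors(), max_c = max_c),
            class = "stain_reference")
}

#' Estimate a stain reference profile from an image
#'
#' @param img H x W x 3 RGB array in \[0, 1\].
#' @param id Reference identifier string.
#' @inheritParams normalize_stains
#' @return A `stain_reference` estimated from the image.
#' @export
stain_reference_from_image <- function(img, id = "estimated", od_floor = 0.15) {
  est <- estimate_stains_(img, od_floor)
  stopif_(is.null(est), "no tissue above the optical-density floor")
  structure(list(id = id, S = est$S, max_c = est$max_c),
            class = "stain_reference")
}

# RGB -> optical density (per channel), guarding the log at 1/256.
rgb_to_od_ <- function(img) {
  if (max(img) > 1) img <- img / 255
  -log10(pmax(img, 1 / 256))
}

# Macenko-style estimation of the two dominant stain vectors and their
# robust concentration maxima. Returns NULL when no pixel clears the floor.
estimate_stains_ <- function(img, od_floor = 0.15, alpha = 0.01,
                             max_pixels = 100000L) {
  od <- rgb_to_od_(img)
  dim(od) <- c(prod(dim(img)[1:2]), 3L)
  fg <- rowSums(od) > od_floor
  if (sum(fg) < 64L) return(NULL)
  V <- od[fg, , drop = FALSE]
  if (nrow(V) > max_pixels) {
    idx <- round(seq(1L, nrow(V), length.out = max_pixels))
    V <- V[idx, , drop = FALSE]
  }
  # top-2 singular plane of the OD cloud
  e <- eigen(crossprod(V) / nrow(V), symmetric = TRUE)
  B <- e$vectors[, 1:2, drop = FALSE]
  if (sum(B[, 1]) < 0) B[, 1] <- -B[, 1]
  P <- V %*% B
  phi <- atan2(P[, 2], P[, 1])
  q <- quantile(phi, c(alpha, 1 - alpha), names = FALSE)
  v1 <- B %*% c(cos(q[1]), sin(q[1]))
  v2 <- B %*% c(cos(q[2]), sin(q[2]))
  fix_sign <- function(v) if (sum(v) < 0) -v else v
  v1 <- fix_sign(v1); v2 <- fix_sign(v2)
  v1 <- v1 / sqrt(sum(v1^2)); v2 <- v2 / sqrt(sum(v2^2))
  # assign hematoxylin/eosin by similarity to the conventional vectors
  Sref <- he_stain_vectors()
  if (sum(v1 * Sref[, "hematoxylin"]) >= sum(v2 * Sref[, "hematoxylin"])) {
    S <- cbind(hematoxylin = as.numeric(v1), eosin = as.numeric(v2))
  } else {
    S <- cbind(hematoxylin = as.numeric(v2), eosin = as.numeric(v1))
  }
  C <- solve(crossprod(S), t(S) %*% t(V))          # 2 x n concentrations
  C[C < 0] <- 0
  max_c <- c(hematoxylin = quantile(C[1, ], 0.99, names = FALSE),
             eosin = quantile(C[2, ], 0.99, names = FALSE))
  list(S = S, max_c = max_c, fg = fg)
}

#' Normalize stain appearance of an H&E image
#'
#' Converts the image to optical density, estimates its two dominant stain
#' vectors (Macenko-style: extreme angles in the top-2 singular plane of
#' the OD cloud), unmixes per-pixel hematoxylin/eosin concentrations,
#' rescales each stain to the reference profile's robust maxima, and
#' reconstructs RGB with the reference stain vectors. Glass (near-zero OD)
#' maps back to near-white.
#'
#' @param img H x W x 3 RGB array in \[0, 1\] (or 0-255).
#' @param reference A `stain_reference` (default [he_reference()]).
#' @param od_floor Total-OD threshold below which a pixel is treated as
#'   glass and excluded from stain estimation.
#' @return A `stain_normalized_image`: list with `rgb` (normalized raster),
#'   `h` and `e` (per-pixel stain concentration rasters, >= 0),
#'   `reference_id`, and `no_tissue` flag. When no pixel clears the OD
#'   floor the input is passed through with `no_tissue = TRUE`.
#' @export
normalize_stains <- function(img, reference = he_reference(), od_floor = 0.15) {
  stopif_(length(dim(img)) != 3L || dim(img)[3] != 3L,
          "img must be an H x W x 3 RGB array")
  if (max(img) > 1) img <- img / 255
  h <- dim(img)[1]; w <- dim(img)[2]
  est <- estimate_stains_(img, od_floor)
  if (is.null(est)) {
    out <- list(rgb = img, h = matrix(0, h, w), e = matrix(0, h, w),
                reference_id = reference$id, no_tissue = TRUE)
    class(out) <- "stain_normalized_image"
    return(out)
  }
  od <- rgb_to_od_(img)
  dim(od) <- c(h * w, 3L)
  C <- solve(crossprod(est$S), t(est$S) %*% t(od))  # 2 x (h*w)
  C[C < 0] <- 0
  scale <- reference$max_c / pmax(est$max_c, 1e-8)
  C <- C * scale
  od_new <- reference$S %*% C                        # 3 x (h*w)
  rgb <- 10^(-t(od_new))
  dim(rgb) <- c(h, w, 3L)
  rgb <- pmin(pmax(rgb, 0), 1)
  out <- list(rgb = rgb,
              h = matrix(C[1, ], h, w),
              e = matrix(C[2, ], h, w),
              reference_id = reference$id,
              no_tissue = FALSE)
  class(out) <- "stain_normalized_image"
  out
}

#' Tissue/glass mask of a normalized image
#'
#' A pixel is tissue iff its total optical density (from the normalized
#' RGB) exceeds `od_threshold`; connected components smaller than
#' `min_object_px` pixels are then removed.
#'
#' @param x A `stain_normalized_image` (or plain RGB array).
#' @param od_threshold Total-OD tissue threshold.
#' @param min_object_px Minimum connected-component area kept, in pixels.
#' @return Logical matrix with the image's spatial dimensions.
#' @export
tissue_mask <- function(x, od_threshold = 0.15, min_object_px = 64L) {
  rgb <- if (inherits(x, "stain_normalized_image")) x$rgb else x
  if (inherits(x, "stain_normalized_image") && isTRUE(x$no_tissue)) {
    return(matrix(FALSE, dim(rgb)[1], dim(rgb)[2]))
  }
  od <- rgb_to_od_(rgb)
  mask <- od[, , 1] + od[, , 2] + od[, , 3] > od_threshold
  if (min_object_px > 1L && any(mask)) {
    lbl <- EBImage::bwlabel(EBImage::Image(mask * 1))
    counts <- tabulate(as.integer(lbl@.Data))
    keep <- which(counts >= min_object_px)
    mask <- matrix(as.integer(lbl@.Data) %in% keep, nrow(mask), ncol(mask))
  }
  mask
}

#' Tile an image into square regions obeying a tissue-fraction rule
#'
#' Candidate top-left offsets are every multiple of `stride_px` from (0, 0)
#' such that the region fits entirely inside the image (0-based, row-major
#' convention). A region is kept iff the mean of `mask` over its footprint
#' is at least `min_tissue_fraction`. Mirrors the study design: 800x800
#' regions, stride 800 (non-overlapping) at training time and 400
#' (overlapping) at test time, >= 50% tissue.
#'
#' @param mask Logical tissue mask (or a `stain_normalized_image`, whose
#'   [tissue_mask()] is computed).
#' @param region_size_px Region side in pixels.
#' @param stride_px Offset stride in pixels.
#' @param min_tissue_fraction Minimum mean tissue coverage of a kept region.
#' @return A `region_grid`: list with the grid parameters and `regions`, a
#'   data frame of `row_offset`, `col_offset`, `tissue_fraction`. If the
#'   image is smaller than the region size, an empty grid with a warning.
#' @export
extract_regions <- function(mask, region_size_px = 800L, stride_px = 400L,
                            min_tissue_fraction = 0.5) {
  if (inherits(mask, "stain_normalized_image")) mask <- tissue_mask(mask)
  stopif_(stride_px < 1L, "stride_px must be >= 1")
  H <- nrow(mask); W <- ncol(mask)
  empty <- data.frame(row_offset = integer(0), col_offset = integer(0),
                      tissue_fraction = numeric(0))
  grid <- list(region_size_px = as.integer(region_size_px),
               stride_px = as.integer(stride_px),
               min_tissue_fraction = min_tissue_fraction,
               image_dim = c(H, W),
               regions = empty)
  class(grid) <- "region_grid"
  if (region_size_px > H || region_size_px > W) {
    warning("image smaller than region_size_px; core skipped (empty grid)")
    return(grid)
  }
  r_off <- seq(0L, H - region_size_px, by = stride_px)
  c_off <- seq(0L, W - region_size_px, by = stride_px)
  S <- integral_image_(mask * 1)
  cand <- expand.grid(row_offset = r_off, col_offset = c_off,
                      KEEP.OUT.ATTRS = FALSE)
  area <- as.numeric(region_size_px)^2
  frac <- mapply(function(r, c) {
    integral_sum_(S, r + 1L, r + region_size_px, c + 1L, c + region_size_px) / area
  }, cand$row_offset, cand$col_offset)
  keep <- frac >= min_tissue_fraction
  regions <- cand[keep, , drop = FALSE]
  regions$tissue_fraction <- frac[keep]
  # row-major ordering: by row offset, then column offset
  regions <- regions[order(regions$row_offset, regions$col_offset), , drop = FALSE]
  rownames(regions) <- NULL
  grid$regions <- regions
  grid
}

#' Serialize a region grid as TSV
#'
#' @param grid A `region_grid`.
#' @param core_id Core identifier written with every row.
#' @param path Output TSV path.
#' @return `path` invisibly.
#' @export
write_region_grid <- function(grid, core_id, path) {
  df <- cbind(data.frame(core_id = core_id), grid$regions)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
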