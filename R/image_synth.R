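# Procedural H&E core images: circular tissue disc on glass, Beer-Lambert
# color model with standard hematoxylin/eosin optical-density vectors.

# Unit-norm H&E stain OD vectors (RGB order), conventional values.
he_stain_vectors <- function() {
  S <- cbind(hematoxylin = c(0.65, 0.70, 0.29),
             eosin       = c(0.07, 0.99, 0.11))
  sweep(S, 2L, sqrt(colSums(S^2)), "/")
}

# Grade-dependent nuclear texture parameters: blobs per 1024^2 image and
# nucleus gaussian sigma in pixels (20x scale, ~0.5 um/px).
grade_texture_params_ <- function(grade_bin) {
  if (identical(grade_bin, "high")) {
    list(blob_density = 1000, nucleus_sigma = 5.5, blob_amp = 1.0)
  } else {
    list(blob_density = 400, nucleus_sigma = 4.0, blob_amp = 0.8)
  }
}

# Smooth random field in [0,1] via a coarse grid upscaled bilinearly.
smooth_field_ <- function(side, coarse = 16L) {
  g <- matrix(runif(coarse * coarse), coarse, coarse)
  EBImage::resize(EBImage::Image(g), w = side, h = side)@.Data
}

#' Synthesize a procedural H&E core image
#'
#' Renders a circular tissue disc on a near-white glass background. Tissue
#' is modeled in stain-concentration space: a smooth eosin (cytoplasm/
#' stroma) field plus nucleus-like hematoxylin blobs whose density and size
#' depend on the patient's grade, converted to RGB through a Beer-Lambert
#' mixture of standard hematoxylin/eosin optical-density vectors. A few
#' circular lumen-like holes are punched so tissue does not fill the disc.
#' Deterministic given `seed`.
#'
#' @param record One-row patient record with at least `grade_bin`.
#' @param side_px Image side in pixels (>= 256).
#' @param seed Integer seed.
#' @return `side_px` x `side_px` x 3 numeric array in \[0, 1\] with
#'   attributes `tissue_truth` (logical ground-truth tissue mask),
#'   `blob_density`, `n_blobs`, `nucleus_sigma`.
#' @export
synthesize_core_image <- function(record, side_px = 1024L, seed = 1L) {
  stopif_(side_px < 256L, "side_px must be >= 256")
  s <- as.integer(side_px)
  pars <- grade_texture_params_(record$grade_bin)
  with_seed_(seed, {
    ctr <- (s + 1) / 2
    R <- 0.47 * s
    rows <- matrix(seq_len(s), s, s)
    cols <- matrix(seq_len(s), s, s, byrow = TRUE)
    dist2 <- (rows - ctr)^2 + (cols - ctr)^2
    disc <- dist2 <= R^2

    # eosin background: smooth stromal field inside the disc
    C_e <- (0.28 + 0.22 * smooth_field_(s)) * disc

    # lumen-like holes
    holes <- matrix(FALSE, s, s)
    n_holes <- max(3L, round(8 * (s / 1024)^2))
    for (i in seq_len(n_holes)) {
      th <- runif(1, 0, 2 * pi); rr <- sqrt(runif(1)) * 0.8 * R
      hc <- c(ctr + rr * cos(th), ctr + rr * sin(th))
      hr <- runif(1, s / 60, s / 30)
      holes <- holes | ((rows - hc[1])^2 + (cols - hc[2])^2 <= hr^2)
    }
    C_e[holes] <- 0

    # hematoxylin: nucleus-like gaussian blobs stamped within the disc
    C_h <- matrix(0, s, s)
    n_blobs <- round(pars$blob_density * (s / 1024)^2)
    sg <- pars$nucleus_sigma
    half <- ceiling(3 * sg)
    kern_ax <- seq(-half, half)
    kern <- exp(-outer(kern_ax^2, kern_ax^2, "+") / (2 * sg^2))
    th <- runif(n_blobs, 0, 2 * pi)
    rr <- sqrt(runif(n_blobs)) * 0.92 * R
    bc_r <- round(ctr + rr * cos(th))
    bc_c <- round(ctr + rr * sin(th))
    amp <- pars$blob_amp * runif(n_blobs, 0.7, 1.3)
    for (i in seq_len(n_blobs)) {
      r0 <- max(1L, bc_r[i] - half); r1 <- min(s, bc_r[i] + half)
      c0 <- max(1L, bc_c[i] - half); c1 <- min(s, bc_c[i] + half)
      kr <- (r0:r1) - bc_r[i] + half + 1L
      kc <- (c0:c1) - bc_c[i] + half + 1L
      C_h[r0:r1, c0:c1] <- C_h[r0:r1, c0:c1] + amp[i] * kern[kr, kc]
    }
    C_h[!disc | holes] <- 0

    S <- he_stain_vectors()
    img <- array(0, c(s, s, 3L))
    for (ch in 1:3) {
      od <- C_h * S[ch, "hematoxylin"] + C_e * S[ch, "eosin"]
      img[, , ch] <- 10^(-od)
    }
    # glass: faint sensor noise so the background is near- but not pure white
    glass_noise <- matrix(runif(s * s, 0, 0.02), s, s)
    for (ch in 1:3) {
      v <- img[, , ch]
      v[!disc] <- 1 - glass_noise[!disc]
      img[, , ch] <- pmin(pmax(v, 0), 1)
    }
    attr(img, "tissue_truth") <- disc & !holes
    attr(img, "blob_density") <- pars$blob_density
    attr(img, "n_blobs") <- n_blobs
    attr(img, "nucleus_sigma") <- sg
    img
  })
}

#' Read or write an RGB image
#'
#' Thin wrappers over the `png` (and optionally `tiff`) readers returning
#' H x W x 3 numeric arrays in \[0, 1\].
#'
#' @param path File path (`.png`, `.tif`/`.tiff`).
#' @param img H x W x 3 array in \[0, 1\].
#' @return The image array, or `path` invisibly for the writer.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("reading TIFF requires the 'tiff' package")
    }
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img
}

#' @rdname read_image
#' @export
write_image <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}
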