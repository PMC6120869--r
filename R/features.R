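# Region feature extraction: pluggable backend producing a spatial grid of
# d-dimensional vectors at 1/8 image resolution, pooled per region.

#' Feature extractor specification
#'
#' @param backend `"filterbank"` (deterministic multi-scale texture/
#'   intensity statistics, no external weights) or `"cnn_intermediate"`
#'   (intermediate convolutional activations of a transferred CNN; requires
#'   a weights source and a runtime, otherwise errors instructing use of
#'   the filter bank).
#' @param d Output feature dimension (vectors padded/truncated to `d`).
#' @param layer_tag CNN layer tag (cnn backend only).
#' @param weights_source Path/identifier of pretrained CNN weights, or
#'   `NULL`.
#' @return An `extractor_spec`.
#' @export
extractor_spec <- function(backend = c("filterbank", "cnn_intermediate"),
                           d = 512L, layer_tag = "conv4",
                           weights_source = NULL) {
  backend <- match.arg(backend)
  spec <- list(backend = backend, d = as.integer(d), layer_tag = layer_tag,
               weights_source = weights_source, downsample = 8L)
  class(spec) <- "extractor_spec"
  spec
}

# Multi-scale statistic rasters for one stain concentration channel:
# identity, gradient magnitude, and difference-of-gaussian responses
# (positive part and square) at sigma = 1, 2, 4.
channel_stat_rasters_ <- function(ch, scales = c(1, 2, 4)) {
  H <- nrow(ch); W <- ncol(ch)
  gx <- rbind(abs(ch[-1L, , drop = FALSE] - ch[-H, , drop = FALSE]), 0)
  gy <- cbind(abs(ch[, -1L, drop = FALSE] - ch[, -W, drop = FALSE]), 0)
  out <- list(raw = ch, grad = gx + gy)
  # gaussian blur saturates to the global mean when the kernel would not
  # fit inside the raster (tiny regions)
  blur <- function(m, sigma) {
    if (2 * ceiling(3 * sigma) + 1 > min(dim(m))) {
      return(matrix(mean(m), nrow(m), ncol(m)))
    }
    EBImage::gblur(EBImage::Image(m), sigma = sigma)@.Data
  }
  for (sg in scales) {
    dog <- blur(ch, sg) - blur(ch, 2 * sg)
    out[[paste0("dogpos", sg)]] <- pmax(dog, 0)
    out[[paste0("dog2", sg)]] <- dog * dog
  }
  out
}

#' Spatial feature map of a normalized image
#'
#' Converts a stain-normalized image into a grid of feature vectors at 1/8
#' of the image resolution (`floor(H/8) x floor(W/8)`), mirroring the
#' downsampling of the fourth convolutional block of a VGG-style network.
#' The `filterbank` backend computes, per 8x8 cell, the mean and standard
#' deviation of each stain concentration channel, mean gradient magnitude,
#' difference-of-gaussian blob responses at three scales, and the RGB
#' channel means; vectors are zero-padded to dimension `d`. Deterministic.
#' The `cnn_intermediate` backend errors unless pretrained weights and a
#' runtime are available, instructing use of the filter bank.
#'
#' @param x A `stain_normalized_image` (or RGB array, which is normalized
#'   first).
#' @param spec An [extractor_spec()].
#' @return A `feature_map`: list with `F` (grid array gh x gw x n_stats),
#'   `d` (declared dimension; trailing dimensions are implicit zeros),
#'   `downsample`, `image_dim`.
#' @export
extract_feature_map <- function(x, spec = extractor_spec()) {
  if (spec$backend == "cnn_intermediate") {
    if (is.null(spec$weights_source) || !file.exists(spec$weights_source)) {
      stop("cnn_intermediate backend: pretrained weights unavailable; ",
           "use extractor_spec(backend = \"filterbank\") instead",
           call. = FALSE)
    }
    stop("cnn_intermediate backend: no CNN runtime is available in this ",
         "installation; use extractor_spec(backend = \"filterbank\")",
         call. = FALSE)
  }
  if (!inherits(x, "stain_normalized_image")) x <- normalize_stains(x)
  f <- spec$downsample
  H <- dim(x$rgb)[1]; W <- dim(x$rgb)[2]
  stopif_(H < f || W < f, "image smaller than one grid cell")
  planes <- list()
  for (ch_name in c("h", "e")) {
    st <- channel_stat_rasters_(x[[ch_name]])
    planes[[paste0(ch_name, "_mean")]] <- block_mean_(st$raw, f)
    planes[[paste0(ch_name, "_sd")]] <- block_sd_(st$raw, f)
    planes[[paste0(ch_name, "_grad")]] <- block_mean_(st$grad, f)
    for (nm in grep("^dog", names(st), value = TRUE)) {
      planes[[paste0(ch_name, "_", nm)]] <- block_mean_(st[[nm]], f)
    }
  }
  for (ch in 1:3) {
    planes[[paste0("rgb", ch)]] <- block_mean_(x$rgb[, , ch], f)
  }
  Fa <- array(unlist(planes, use.names = FALSE),
              c(nrow(planes[[1]]), ncol(planes[[1]]), length(planes)))
  fm <- list(F = Fa, feature_names = names(planes), d = spec$d,
             downsample = f, image_dim = c(H, W), backend = spec$backend)
  class(fm) <- "feature_map"
  fm
}

#' Pool a feature map over tiled regions into a feature bag
#'
#' Each kept region's vector is the arithmetic mean of the grid cells its
#' footprint covers. Pixel offsets map to grid coordinates by dividing by
#' the downsampling factor, flooring at the start and ceiling at the end of
#' the footprint so every contributing cell is included. Pooled vectors are
#' zero-padded to the map's declared dimension `d`.
#'
#' @param fmap A `feature_map` (or plain gh x gw x k array for testing, in
#'   which case `downsample` is taken as 1 and `d = k`).
#' @param grid A `region_grid` from [extract_regions()].
#' @param patient_id,core_id Identifiers recorded in the bag.
#' @return A `feature_bag` with one row per kept region, ordered as the
#'   grid. Errors if the grid is empty.
#' @export
pool_region_features <- function(fmap, grid, patient_id = "unknown",
                                 core_id = 1L) {
  if (!inherits(fmap, "feature_map")) {
    a <- fmap
    stopifnot(length(dim(a)) == 3L)
    fmap <- list(F = a, d = dim(a)[3], downsample = 1L,
                 image_dim = dim(a)[1:2])
    class(fmap) <- "feature_map"
  }
  regions <- grid$regions
  stopif_(nrow(regions) == 0L, "empty region grid: no regions to pool")
  f <- fmap$downsample
  gh <- dim(fmap$F)[1]; gw <- dim(fmap$F)[2]; k <- dim(fmap$F)[3]
  size <- grid$region_size_px
  X <- matrix(0, nrow(regions), fmap$d)
  for (i in seq_len(nrow(regions))) {
    r0 <- floor(regions$row_offset[i] / f) + 1L
    c0 <- floor(regions$col_offset[i] / f) + 1L
    r1 <- min(gh, as.integer(ceiling((regions$row_offset[i] + size) / f)))
    c1 <- min(gw, as.integer(ceiling((regions$col_offset[i] + size) / f)))
    stopif_(r0 > gh || c0 > gw, "region offset outside the feature grid")
    block <- fmap$F[r0:r1, c0:c1, , drop = FALSE]
    X[i, seq_len(k)] <- apply(block, 3L, mean)
  }
  bag <- list(patient_id = patient_id,
              entries = data.frame(core_id = core_id,
                                   region_row = regions$row_offset,
                                   region_col = regions$col_offset),
              X = X, instance_class = NULL, d = fmap$d)
  class(bag) <- "feature_bag"
  bag
}

#' Filter-bank feature vector of one region
#'
#' The deterministic statistics of [extract_feature_map()] computed over a
#' whole region raster (stain means and dispersions, gradient energy,
#' difference-of-gaussian blob responses at three scales, RGB means),
#' zero-padded to dimension `d`.
#'
#' @param region A `stain_normalized_image` covering just the region, or a
#'   list with `h`, `e` (and optionally `rgb`) rasters.
#' @param d Output dimension.
#' @return Numeric vector of length `d`.
#' @export
filterbank_features <- function(region, d = 512L) {
  h <- region$h; e <- region$e
  stopifnot(is.matrix(h), is.matrix(e))
  vals <- c()
  for (ch in list(h, e)) {
    st <- channel_stat_rasters_(ch)
    vals <- c(vals, mean(st$raw), sd(as.numeric(st$raw)), mean(st$grad),
              vapply(st[grep("^dog", names(st))], mean, numeric(1)))
  }
  if (!is.null(region$rgb)) {
    vals <- c(vals, apply(region$rgb, 3L, mean))
  } else {
    vals <- c(vals, rep(0, 3))
  }
  vals[is.na(vals)] <- 0
  out <- numeric(d)
  out[seq_len(min(d, length(vals)))] <- vals[seq_len(min(d, length(vals)))]
  out
}

# Combine per-core bags of one patient into a single patient bag.
combine_bags_ <- function(bags, patient_id) {
  stopifnot(length(bags) >= 1L)
  bag <- list(patient_id = patient_id,
              entries = do.call(rbind, lapply(bags, `[[`, "entries")),
              X = do.call(rbind, lapply(bags, `[[`, "X")),
              instance_class = NULL,
              d = bags[[1]]$d)
  rownames(bag$entries) <- NULL
  class(bag) <- "feature_bag"
  bag
}
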