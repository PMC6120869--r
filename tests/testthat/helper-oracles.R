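# Shared fixtures and independent oracles used across test files.

# Brute-force interpolated inverse CDF: for level p, h = (n-1)p + 1 and the
# value is linearly interpolated between the flooring/ceiling order
# statistics. Independent of stats::quantile.
quantile_oracle <- function(x, levels) {
  xs <- sort(x)
  n <- length(xs)
  vapply(levels, function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    xs[lo] + (h - lo) * (xs[hi] - xs[lo])
  }, numeric(1))
}

# Small cohort config for fast model tests.
small_cfg <- function(n = 80, d = 16, rpc = 6, seed = 7, ...) {
  cohort_config(n_patients = n, feature_dim = d, regions_per_core = rpc,
                seed = seed, ...)
}

# Hand-built ensemble whose members are constant maps, for arithmetic
# contracts of predict_instance_prob.
constant_ensemble <- function(values, d = 3L) {
  members <- lapply(values, function(v) {
    list(w = rep(0, d), b = 0,
         iso = structure(list(x = 0, y = v), class = "isotonic_map"))
  })
  structure(list(members = members,
                 standardization = list(mu = rep(0, d), sd = rep(1, d)),
                 d = d),
            class = "instance_ensemble")
}

# Minimal feature bag.
make_bag <- function(X, core_id = 1L, patient_id = "P", d = ncol(X)) {
  structure(list(patient_id = patient_id,
                 entries = data.frame(core_id = core_id,
                                      region_row = seq_len(nrow(X)) - 1L,
                                      region_col = 0L),
                 X = X, instance_class = NULL, d = d),
            class = "feature_bag")
}

# One-row patient record for image synthesis.
dummy_record <- function(grade_bin = "high", id = "P1", n_cores = 1L) {
  data.frame(patient_id = id, grade_bin = grade_bin, n_cores = n_cores,
             stringsAsFactors = FALSE)
}

# Beer-Lambert forward simulator with known stain vectors/concentrations;
# the independent oracle for stain unmixing.
forward_he_image <- function(C_h, C_e, S = NULL) {
  if (is.null(S)) {
    S <- cbind(c(0.65, 0.70, 0.29), c(0.07, 0.99, 0.11))
    S <- sweep(S, 2, sqrt(colSums(S^2)), "/")
  }
  H <- nrow(C_h); W <- ncol(C_h)
  img <- array(0, c(H, W, 3))
  for (ch in 1:3) img[, , ch] <- 10^(-(C_h * S[ch, 1] + C_e * S[ch, 2]))
  pmin(pmax(img, 0), 1)
}
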