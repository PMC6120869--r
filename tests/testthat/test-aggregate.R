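# Quantile signatures, the patient-level model, cut points.

test_that("quantile signature matches its defining conventions", {
  s <- quantile_signature(rep(0.5, 7))
  expect_equal(as.numeric(s), rep(0.5, 16))
  s2 <- quantile_signature(c(0, 1))
  expect_equal(as.numeric(s2), (0:15) / 15)
  set.seed(3)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    sig <- quantile_signature(p)
    expect_true(all(diff(sig) >= -1e-12))
    expect_equal(sig[1], min(p))
    expect_equal(sig[16], max(p))
    expect_equal(as.numeric(sig), quantile_oracle(p, (0:15) / 15),
                 tolerance = 1e-12)
  }
  expect_error(quantile_signature(numeric(0)), "empty")
  # midpoint convention stays inside the extremes
  sm <- quantile_signature(c(0, 1), convention = "midpoint")
  expect_equal(attr(sm, "levels"), ((1:16) - 0.5) / 16)
})

test_that("signatures are invariant to permutation and duplication", {
  set.seed(11)
  p <- runif(23)
  expect_equal(quantile_signature(p), quantile_signature(sample(p)))
  # duplication invariance is exact when n = 1 (mod 15): interpolation
  # positions then stay inside replicated order-statistic blocks
  p16 <- runif(16)
  expect_equal(as.numeric(quantile_signature(p16)),
               as.numeric(quantile_signature(rep(p16, 2))), tolerance = 1e-12)
  # and holds asymptotically (O(range/n)) for general n
  p500 <- runif(500)
  expect_equal(as.numeric(quantile_signature(p500)),
               as.numeric(quantile_signature(rep(p500, 2))), tolerance = 0.01)
})

test_that("patient model separates a separable cohort and controls go flat", {
  cfg <- small_cfg(n = 90, d = 12, rpc = 6, seed = 33,
                   effect_size = 3, heterogeneity = 0.1)
  coh <- generate_cohort(cfg)
  bags <- synthesize_cohort_bags(coh, "er", cfg)
  tr <- coh$split == "train"
  y_tr <- task_truth(coh[tr, ], "er")
  ens <- fit_instance_ensemble(bags[tr], y_tr, seed = 3)
  sigs <- t(sapply(bags[tr], function(b)
    quantile_signature(predict_instance_prob(ens, b))))
  pipe <- fit_patient_model(sigs, y_tr, task = "er", ensemble = ens, seed = 4)
  y_te <- task_truth(coh[!tr, ], "er")
  pr <- sapply(bags[!tr], function(b) predict_patient(pipe, b))
  expect_true(all(pr >= 0 & pr <= 1))
  expect_gte(mean((pr > 0.5) == (y_te == 1)), 0.9)
  # no-signal control: a featureless cohort cannot beat the majority rate
  cfg0 <- small_cfg(n = 90, d = 12, rpc = 6, seed = 33,
                    effect_size = 0, grade_effect = 0)
  bags0 <- synthesize_cohort_bags(coh, "er", cfg0)
  ens0 <- fit_instance_ensemble(bags0[tr], y_tr, seed = 3)
  sigs0 <- t(sapply(bags0[tr], function(b)
    quantile_signature(predict_instance_prob(ens0, b))))
  pipe0 <- fit_patient_model(sigs0, y_tr, task = "er", ensemble = ens0, seed = 4)
  pr0 <- sapply(bags0[!tr], function(b) predict_patient(pipe0, b))
  acc0 <- mean((pr0 > 0.5) == (y_te == 1))
  maj <- max(mean(y_te), 1 - mean(y_te))
  expect_lt(abs(acc0 - maj), 3 * sqrt(maj * (1 - maj) / length(y_te)) + 0.05)
  expect_error(fit_patient_model(sigs, rep(1, nrow(sigs))), "both classes")
})

test_that("duplicating the training set leaves the decision function unchanged", {
  set.seed(9)
  X <- matrix(runif(40 * 16), 40, 16)
  y <- rep(0:1, 20)
  p1 <- fit_patient_model(X, y, C_grid = 0.1, seed = 2)
  p2 <- fit_patient_model(rbind(X, X), c(y, y), C_grid = 0.1, seed = 2)
  expect_equal(p1$w, p2$w, tolerance = 1e-4)
  expect_equal(p1$b, p2$b, tolerance = 1e-4)
})

test_that("patient prediction pools cores exchangeably", {
  set.seed(15)
  sigfit <- matrix(runif(40 * 16), 40, 16)
  pipe <- fit_patient_model(t(apply(sigfit, 1, sort)), rep(0:1, 20), seed = 6)
  probs_core <- runif(16)  # n = 1 (mod 15): replication-exact signature
  # identical cores: pooled probability equals the single-core probability
  expect_equal(predict_patient(pipe, rep(probs_core, 3)),
               predict_patient(pipe, probs_core))
  # permuting region/core order changes nothing
  expect_equal(predict_patient(pipe, sample(probs_core)),
               predict_patient(pipe, probs_core))
  # mixed cores (3 like A, 1 like B): patient probability between extremes
  pa <- rep(0.9, 10); pb <- rep(0.1, 10)
  pooled <- predict_patient(pipe, c(pa, pa, pa, pb))
  lo <- min(predict_patient(pipe, pa), predict_patient(pipe, pb))
  hi <- max(predict_patient(pipe, pa), predict_patient(pipe, pb))
  expect_gte(pooled, lo)
  expect_lte(pooled, hi)
  # unscorable patient: NA with a warning, not silence
  expect_warning(out <- predict_patient(pipe, numeric(0)), "unscorable")
  expect_true(is.na(out))
})

test_that("core-level prediction restricts to one core's regions", {
  set.seed(25)
  pipe <- fit_patient_model(matrix(runif(40 * 16), 40, 16), rep(0:1, 20), seed = 2)
  X <- matrix(rnorm(12 * 16), 12, 16)
  bag <- make_bag(X, core_id = rep(1:3, each = 4))
  ens <- constant_ensemble(c(0.1, 0.3, 0.5, 0.7, 0.9), d = 16)
  pipe$ensemble <- ens
  p1 <- predict_core(pipe, bag, core_id = 1)
  p1b <- predict_core(pipe, bag, core_id = 2)
  expect_equal(p1, p1b)  # constant ensemble: identical cores score identically
  # single-region core: constant signature
  single <- make_bag(matrix(rnorm(16), 1, 16), core_id = 9L)
  expect_equal(predict_core(pipe, single, core_id = 9),
               hemil:::score_signature_(pipe, rep(0.5, 16)))
  expect_equal(predict_core(pipe, c(0.2, 0.8), method = "mean_prob"), 0.5)
})

test_that("classification uses strict greater-than task cut points", {
  expect_equal(classify(0.80, "grade"), "low-intermediate")
  expect_equal(classify(0.801, "grade"), "high")
  expect_equal(classify(0.50, "er"), "negative")
  expect_equal(classify(0.51, "er"), "positive")
  expect_equal(classify(0.60, "basal"), "non-basal")
  expect_equal(classify(0.21, "ror"), "high")
  expect_equal(classify(0.11, "histology"), "lobular")
  expect_error(classify(0.5, "proliferation"), "unknown task")
  # monotone: raising a probability never flips positive -> negative
  p <- seq(0, 1, 0.01)
  calls <- classify(p, "grade") == "high"
  expect_true(all(diff(calls) >= 0))
})

test_that("cut-point selection maximizes Youden's J with a low-tie rule", {
  probs <- c(rep(0.1, 10), rep(0.9, 10))
  truth <- rep(0:1, each = 10)
  expect_equal(select_cut_point(probs, truth), 0.1)
  # signal-free probabilities still give a deterministic answer
  set.seed(41)
  p0 <- runif(50); t0 <- rbinom(50, 1, 0.5)
  expect_identical(select_cut_point(p0, t0), select_cut_point(p0, t0))
  # bimodal grade-like histogram: the cut lands between the modes
  set.seed(42)
  pm <- c(rbeta(200, 2, 12), rbeta(100, 12, 2))
  tm <- rep(0:1, c(200, 100))
  cut <- select_cut_point(pm, tm)
  expect_gt(cut, quantile(pm[tm == 0], 0.5))
  expect_lt(cut, quantile(pm[tm == 1], 0.5))
  expect_error(select_cut_point(p0, rep(1, 50)), "both classes")
})
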