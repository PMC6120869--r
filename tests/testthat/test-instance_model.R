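# Sample weighting and the calibrated instance ensemble.

test_that("inverse-count weights equalize cell totals", {
  grade <- rep(c("low-intermediate", "low-intermediate", "high", "high"),
               c(10, 20, 30, 40))
  cls <- rep(c("pos", "neg", "pos", "neg"), c(10, 20, 30, 40))
  w <- compute_sample_weights(cls, grade, "grade_by_class")
  expect_equal(mean(w), 1)
  totals <- tapply(w, paste(grade, cls), sum)
  expect_true(diff(range(totals)) < 1e-12)
  # per-sample weights in ratio 12:6:4:3 (inverse of 10:20:30:40)
  uw <- unique(round(w / min(w) * 3, 9))
  expect_setequal(uw, c(12, 6, 4, 3))

  w_eq <- compute_sample_weights(rep(c("a", "b"), each = 5))
  expect_equal(w_eq, rep(1, 10))

  # singleton cells: the lone sample carries the whole cell total
  grade2 <- c("high", "high", rep("low-intermediate", 8))
  cls2 <- c("pos", "neg", rep(c("pos", "neg"), each = 4))
  w2 <- compute_sample_weights(cls2, grade2, "grade_by_class")
  totals2 <- tapply(w2, paste(grade2, cls2), sum)
  expect_true(diff(range(totals2)) < 1e-12)
  expect_equal(w2[1], sum(w2[grade2 == "low-intermediate" & cls2 == "pos"]))
})

test_that("empty weighting cells are rejected by name", {
  grade <- factor(rep("high", 4), levels = c("high", "low-intermediate"))
  cls <- rep(c("pos", "neg"), 2)
  expect_error(compute_sample_weights(cls, grade, "grade_by_class"),
               "low-intermediate")
})

test_that("ensemble separates separable bags and is seed-deterministic", {
  cfg <- small_cfg(n = 70, d = 12, rpc = 6, seed = 19,
                   heterogeneity = 0, effect_size = 3)
  coh <- generate_cohort(cfg)
  bags <- synthesize_cohort_bags(coh, "er", cfg)
  tr <- coh$split == "train"
  y_tr <- task_truth(coh[tr, ], "er")
  ens <- fit_instance_ensemble(bags[tr], y_tr, seed = 5)
  expect_length(ens$members, 5)
  # held-out instance AUC on the untouched test split
  te_bags <- bags[!tr]
  y_te <- task_truth(coh[!tr, ], "er")
  probs <- unlist(lapply(te_bags, function(b) predict_instance_prob(ens, b)))
  yy <- rep(y_te, times = vapply(te_bags, function(b) nrow(b$X), integer(1)))
  r <- rank(probs); n1 <- sum(yy == 1); n0 <- sum(yy == 0)
  auc <- (sum(r[yy == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  expect_gt(auc, 0.95)
  ens2 <- fit_instance_ensemble(bags[tr], y_tr, seed = 5)
  expect_identical(lapply(ens$members, `[[`, "w"),
                   lapply(ens2$members, `[[`, "w"))
})

test_that("shuffled labels give chance-level held-out instance AUC", {
  cfg <- small_cfg(n = 70, d = 12, rpc = 6, seed = 23)
  coh <- generate_cohort(cfg)
  bags <- synthesize_cohort_bags(coh, "er", cfg)
  tr <- which(coh$split == "train")
  y <- task_truth(coh, "er")
  set.seed(101)
  y_shuf <- y
  y_shuf[tr] <- sample(y[tr])  # shuffle training labels only
  ens <- fit_instance_ensemble(bags[tr], y_shuf[tr], seed = 7)
  te <- which(coh$split == "test")
  probs <- unlist(lapply(bags[te], function(b) predict_instance_prob(ens, b)))
  yy <- rep(y[te], times = vapply(bags[te], function(b) nrow(b$X), integer(1)))
  r <- rank(probs); n1 <- sum(yy == 1); n0 <- sum(yy == 0)
  auc <- (sum(r[yy == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  expect_lt(abs(auc - 0.5), 0.12)
})

test_that("ensemble probability is the member mean and respects bounds", {
  ens <- constant_ensemble(c(0.2, 0.4, 0.6, 0.8, 1.0))
  bag <- make_bag(matrix(rnorm(6), 2, 3))
  expect_equal(predict_instance_prob(ens, bag), c(0.6, 0.6))
  expect_equal(predict_instance_prob(constant_ensemble(rep(0, 5)), bag), c(0, 0))
  expect_equal(predict_instance_prob(constant_ensemble(rep(1, 5)), bag), c(1, 1))
  # invariance to member ordering
  ens_perm <- constant_ensemble(c(1.0, 0.2, 0.8, 0.4, 0.6))
  expect_equal(predict_instance_prob(ens_perm, bag),
               predict_instance_prob(ens, bag))
  expect_error(predict_instance_prob(ens, make_bag(matrix(0, 2, 4))),
               "dimension")
})

test_that("calibrated member output is non-decreasing in the raw score", {
  set.seed(61)
  scores <- rnorm(400)
  y <- rbinom(400, 1, plogis(2 * scores))
  iso <- hemil:::isotonic_fit_(scores, y)
  scan <- seq(min(scores) - 1, max(scores) + 1, length.out = 1000)
  out <- hemil:::isotonic_predict_(iso, scan)
  expect_true(all(diff(out) >= -1e-12))
  expect_true(all(out >= 0 & out <= 1))
})

test_that("monotone feature shifts give non-decreasing ensemble probability", {
  cfg <- small_cfg(n = 60, d = 8, rpc = 6, seed = 29, effect_size = 3,
                   heterogeneity = 0, grade_effect = 0)
  coh <- generate_cohort(cfg)
  bags <- synthesize_cohort_bags(coh, "er", cfg)
  tr <- coh$split == "train"
  ens <- fit_instance_ensemble(bags[tr], task_truth(coh[tr, ], "er"), seed = 2)
  # scan a 1-D path along the ensemble's own mean discriminant direction
  w_bar <- Reduce(`+`, lapply(ens$members, `[[`, "w")) / 5
  path <- outer(seq(-4, 4, length.out = 200), w_bar / sqrt(sum(w_bar^2)))
  path_raw <- sweep(sweep(path, 2, ens$standardization$sd, "*"),
                    2, ens$standardization$mu, "+")
  p <- predict_instance_prob(ens, path_raw)
  expect_true(all(diff(p) >= -1e-9))
})

test_that("the weighted linear SVM agrees with an independent SVM implementation", {
  set.seed(53)
  n <- 200; d <- 10
  y <- rep(0:1, each = n / 2)
  X <- matrix(rnorm(n * d), n, d)
  X[, 1] <- X[, 1] + (y - 0.5) * 3
  X[, 2] <- X[, 2] + (y - 0.5) * 1.5
  fit <- hemil:::wlsvm_fit_(X, y, C = 1)
  ref <- e1071::svm(X, factor(y), kernel = "linear", cost = 1, scale = FALSE)
  w_ref <- drop(t(ref$coefs) %*% ref$SV)  # orientation depends on level order
  cosine <- sum(fit$w * w_ref) / sqrt(sum(fit$w^2) * sum(w_ref^2))
  expect_gt(abs(cosine), 0.95)
  # both rank a held-out sample identically to high agreement
  Xte <- matrix(rnorm(100 * d), 100, d)
  expect_gt(abs(cor(drop(Xte %*% fit$w), drop(Xte %*% w_ref))), 0.95)
})

test_that("too few patients per class is rejected", {
  cfg <- small_cfg(n = 20, d = 6, rpc = 4, seed = 3)
  coh <- generate_cohort(cfg)
  bags <- synthesize_cohort_bags(coh, "er", cfg)
  y <- task_truth(coh, "er")
  pick <- c(which(y == 1)[1:8], which(y == 0)[1:2])
  expect_error(fit_instance_ensemble(bags[pick], y[pick]), "at least 5")
})
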