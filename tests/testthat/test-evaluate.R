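# Concordance statistics: confusion tables, rates, kappa, chi-square, OR.

test_that("confusion tabulates pairs with the stated orientation", {
  pred <- c("pos", "pos", "neg", "neg", "pos", "neg")
  ref  <- c("pos", "neg", "neg", "pos", "pos", "neg")
  cs <- confusion(pred, ref, positive = "pos")
  # manual tally: a = 2 (neg/neg), b = 1 (neg/pos), c = 1 (pos/neg), d = 2
  expect_equal(unname(cs$counts), matrix(c(2, 1, 1, 2), 2, 2))
  expect_equal(cs$n, 6)

  same <- confusion(rep(c("a", "b"), 5), rep(c("a", "b"), 5), positive = "b")
  expect_equal(unname(same$counts), matrix(c(5, 0, 0, 5), 2, 2))
  opp <- confusion(rep(c("a", "b"), 5), rep(c("b", "a"), 5), positive = "b")
  expect_equal(sum(diag(opp$counts)), 0)

  # missing references are dropped and counted
  cm <- confusion(c("pos", "neg", "pos"), c("pos", NA, "neg"), positive = "pos")
  expect_equal(cm$n, 2)
  expect_equal(cm$n_missing_reference, 1)
  expect_error(confusion(c("a", "b"), c("a"), positive = "a"), "lengths differ")
})

test_that("rates reproduce the published ER and histology values", {
  er <- matrix(c(260, 83, 80, 572), 2, 2)   # rows pred (neg, pos), cols ref
  r <- rates(er)
  expect_equal(round(r[["accuracy"]]), 84)
  expect_equal(round(r[["sensitivity"]]), 88)
  expect_equal(round(r[["specificity"]]), 76)
  hist <- matrix(c(710, 28, 24, 58), 2, 2)
  expect_equal(round(rates(hist)[["accuracy"]]), 94)
  perfect <- matrix(c(7, 0, 0, 5), 2, 2)
  expect_equal(unname(rates(perfect)), c(100, 100, 100))
  # zero reference margin: N/A, as in the high-grade histology stratum
  degen <- matrix(c(442, 5, 0, 0), 2, 2)
  expect_true(is.na(rates(degen)[["sensitivity"]]))
  expect_equal(round(rates(degen)[["specificity"]]), 99)
})

test_that("kappa reproduces published values and satisfies its identities", {
  grade <- matrix(c(118, 45, 8, 117), 2, 2)
  expect_equal(round(cohens_kappa(grade)$kappa, 2), 0.64)
  er <- matrix(c(260, 83, 80, 572), 2, 2)
  ker <- cohens_kappa(er)
  expect_equal(round(ker$kappa, 2), 0.64)
  expect_equal(round(ker$ci, 2), c(0.59, 0.69))
  path <- matrix(c(113, 4, 23, 102), 2, 2)
  kp <- cohens_kappa(path)
  expect_equal(round(kp$kappa, 2), 0.78)
  expect_equal(round(kp$ci, 2), c(0.70, 0.86))
  # identities
  expect_equal(cohens_kappa(matrix(c(30, 0, 0, 20), 2, 2))$kappa, 1)
  expect_equal(cohens_kappa(matrix(c(50, 50, 50, 50), 2, 2))$kappa, 0)
  set.seed(8)
  for (i in 1:10) {
    m <- matrix(sample(1:80, 4, replace = TRUE), 2, 2)
    k1 <- cohens_kappa(m)$kappa
    swap <- m[2:1, 2:1]  # simultaneous row+column label swap
    expect_equal(cohens_kappa(swap)$kappa, k1)
    if (sum(m[1, 2] + m[2, 1]) > 0) expect_lt(k1, 1)
  }
  # degenerate margins (p_e = 1) are undefined
  expect_true(is.na(cohens_kappa(matrix(c(10, 0, 0, 0), 2, 2))$kappa))
  # the Fleiss variant is monotone-sane and differs in general
  kf <- cohens_kappa(er, se = "fleiss")
  expect_equal(kf$kappa, ker$kappa)
  expect_gt(kf$se, 0)
})

test_that("percent agreement reproduces the published grade values", {
  expect_equal(round(percent_agreement(matrix(c(113, 4, 23, 102), 2, 2))), 89)
  expect_equal(round(percent_agreement(matrix(c(118, 45, 8, 117), 2, 2))), 82)
  expect_equal(percent_agreement(matrix(c(9, 0, 0, 4), 2, 2)), 100)
})

test_that("accuracy is the reference-margin-weighted mean of sens and spec", {
  tabs <- cbcs3_tables()
  for (i in seq_len(nrow(tabs))) {
    m <- matrix(c(tabs$a[i], tabs$c[i], tabs$b[i], tabs$d[i]), 2, 2)
    r <- rates(m)
    pos_m <- m[1, 2] + m[2, 2]; neg_m <- m[1, 1] + m[2, 1]
    if (pos_m == 0 || neg_m == 0) next
    expect_equal(r[["accuracy"]],
                 (r[["sensitivity"]] * pos_m + r[["specificity"]] * neg_m) /
                   (pos_m + neg_m))
  }
})

test_that("chi-square homogeneity matches the direct formula", {
  flat <- chi_square_homogeneity(matrix(10, 2, 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  expect_equal(chi_square_homogeneity(matrix(c(30, 60, 20, 40), 2, 2))$statistic, 0)
  m <- matrix(c(20, 10, 5, 25), 2, 2)
  ct <- chi_square_homogeneity(m)
  # direct Pearson formula oracle
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  expect_equal(ct$statistic, sum((m - E)^2 / E))
  expect_equal(ct$df, 1)
  r3 <- chi_square_homogeneity(matrix(c(10, 20, 30, 15, 25, 20), 3, 2))
  expect_equal(r3$df, 2)
  expect_error(chi_square_homogeneity(matrix(c(0, 0, 5, 5), 2, 2)),
               "expected")
})

test_that("odds ratios use ad/bc with Woolf intervals and Haldane fallback", {
  expect_equal(odds_ratio(matrix(c(4, 1, 1, 4), 2, 2))$or, 16)
  flat <- odds_ratio(matrix(10, 2, 2))
  expect_equal(flat$or, 1)
  expect_lt(flat$ci[1], 1); expect_gt(flat$ci[2], 1)
  m <- matrix(c(12, 5, 7, 20), 2, 2)
  o <- odds_ratio(m)
  expect_equal(o$ci,
               exp(log(12 * 20 / (7 * 5)) + c(-1.96, 1.96) * sqrt(1/12 + 1/5 + 1/7 + 1/20)),
               tolerance = 1e-3)
  z <- odds_ratio(matrix(c(5, 0, 3, 8), 2, 2))
  expect_true(z$haldane)
  expect_true(is.finite(z$or))
})

test_that("the bundled concordance tables reproduce the published statistics", {
  out <- cbcs3_concordance()
  row <- function(id) out[out$table_id == id, ]
  g <- row("grade_image")
  expect_equal(g$agreement, 82)
  expect_equal(g$kappa, 0.64)
  expect_equal(g$kappa_lo, 0.55)
  p <- row("grade_pathologists")
  expect_equal(p$agreement, 89)
  expect_equal(p$kappa, 0.78)
  expect_equal(c(p$kappa_lo, p$kappa_hi), c(0.70, 0.86))
  er <- row("er_overall_unweighted")
  expect_equal(c(er$accuracy, er$sensitivity, er$specificity), c(84, 88, 76))
  expect_equal(c(er$kappa, er$kappa_lo, er$kappa_hi), c(0.64, 0.59, 0.69))
  expect_equal(row("er_overall_grade_trained")$accuracy, 80)
  expect_equal(row("basal_overall")$accuracy, 77)
  expect_equal(row("basal_overall")$kappa, 0.47)
  expect_equal(row("ror_overall")$accuracy, 76)
  expect_equal(c(row("ror_overall")$kappa_lo, row("ror_overall")$kappa_hi),
               c(0.40, 0.54))
  h <- row("histology_overall")
  expect_equal(h$accuracy, 94)
  expect_equal(h$kappa, 0.66)
  expect_true(is.na(row("histology_high")$sensitivity))
})
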