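# Concordance statistics between predicted and reference labels.
#
# Orientation convention throughout: 2x2 count matrices have rows =
# prediction (rater 1) and columns = reference (rater 2), ordered
# (negative, positive); counts[2, 2] is the true-positive cell.

#' Cross-tabulate predicted against reference labels
#'
#' Pairs with a missing reference label are dropped and counted.
#'
#' @param predicted,reference Equal-length label vectors (binary).
#' @param positive The positive-class label (used for sensitivity).
#' @return A `confusion_summary`: 2x2 `counts` (rows = prediction, columns
#'   = reference, negative class first), `n`, `n_missing_reference`,
#'   `positive_class`, plus derived `accuracy`, `sensitivity`,
#'   `specificity` (percent), `agreement`, `kappa` and `kappa_ci`.
#' @export
confusion <- function(predicted, reference, positive) {
  stopif_(length(predicted) != length(reference),
          "predicted and reference lengths differ")
  keep <- !is.na(reference)
  n_missing <- sum(!keep)
  predicted <- as.character(predicted)[keep]
  reference <- as.character(reference)[keep]
  lev <- unique(c(reference, predicted))
  stopif_(!positive %in% lev && length(lev) > 2L, "more than two classes")
  negative <- setdiff(lev, positive)
  stopif_(length(negative) > 1L, "more than two classes")
  if (length(negative) == 0L) negative <- paste0("not-", positive)
  f <- function(x) factor(x, levels = c(negative, positive))
  counts <- unclass(table(prediction = f(predicted), reference = f(reference)))
  confusion_summary(counts, positive_class = positive,
                    n_missing_reference = n_missing)
}

#' Summary statistics of a 2x2 count matrix
#'
#' @param counts 2x2 integer matrix, rows = prediction, columns =
#'   reference, negative class first.
#' @param positive_class Label of the positive (second) class.
#' @param n_missing_reference Count of dropped pairs, carried through.
#' @return A `confusion_summary` (see [confusion()]).
#' @export
confusion_summary <- function(counts, positive_class = "positive",
                              n_missing_reference = 0L) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == c(2L, 2L)))
  r <- rates(counts)
  k <- cohens_kappa(counts)
  out <- list(counts = counts, n = sum(counts),
              n_missing_reference = n_missing_reference,
              positive_class = positive_class,
              accuracy = r[["accuracy"]],
              sensitivity = r[["sensitivity"]],
              specificity = r[["specificity"]],
              agreement = percent_agreement(counts),
              kappa = k$kappa, kappa_ci = k$ci)
  class(out) <- "confusion_summary"
  out
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf("Confusion summary (n = %d, positive class = %s)\n",
              x$n, x$positive_class))
  print(x$counts)
  if (x$n_missing_reference > 0L) {
    cat(sprintf("dropped pairs with missing reference: %d\n",
                x$n_missing_reference))
  }
  fmt <- function(v) if (is.na(v)) "N/A" else sprintf("%d", round(v))
  cat(sprintf("accuracy %s%%, sensitivity %s%%, specificity %s%%\n",
              fmt(x$accuracy), fmt(x$sensitivity), fmt(x$specificity)))
  if (is.na(x$kappa)) {
    cat("kappa N/A\n")
  } else {
    cat(sprintf("kappa %.2f (%.2f-%.2f)\n", x$kappa,
                x$kappa_ci[1], x$kappa_ci[2]))
  }
  invisible(x)
}

#' Accuracy, sensitivity, specificity of a 2x2 table
#'
#' Percentages on the 0-100 scale (unrounded; reporting rounds to integer).
#' Sensitivity is the fraction of reference-positive units predicted
#' positive; a zero reference margin yields `NA` (reported as N/A).
#'
#' @inheritParams confusion_summary
#' @return Named numeric vector `accuracy`, `sensitivity`, `specificity`.
#' @export
rates <- function(counts) {
  counts <- as.matrix(counts)
  n <- sum(counts)
  stopif_(n == 0L, "empty table")
  acc <- 100 * (counts[1, 1] + counts[2, 2]) / n
  pos_margin <- counts[1, 2] + counts[2, 2]
  neg_margin <- counts[1, 1] + counts[2, 1]
  sens <- if (pos_margin == 0) NA_real_ else 100 * counts[2, 2] / pos_margin
  spec <- if (neg_margin == 0) NA_real_ else 100 * counts[1, 1] / neg_margin
  c(accuracy = acc, sensitivity = sens, specificity = spec)
}

#' Percent agreement of a 2x2 table
#'
#' @inheritParams confusion_summary
#' @return Diagonal share of the table as a percentage (0-100, unrounded).
#' @export
percent_agreement <- function(counts) {
  counts <- as.matrix(counts)
  stopif_(sum(counts) == 0L, "empty table")
  100 * sum(diag(counts)) / sum(counts)
}

#' Cohen's kappa with 95% confidence interval
#'
#' kappa = (p_o - p_e) / (1 - p_e) with chance agreement p_e from the
#' marginal products. The default CI uses the simple asymptotic standard
#' error sqrt(p_o (1 - p_o) / (n (1 - p_e)^2)); `se = "fleiss"` uses the
#' Fleiss-Cohen-Everitt large-sample variance instead. Degenerate margins
#' (p_e = 1) yield `NA`.
#'
#' @inheritParams confusion_summary
#' @param se Standard-error formula, `"simple"` or `"fleiss"`.
#' @param conf_level Confidence level.
#' @return List with `kappa`, `se`, `ci` (length-2 vector).
#' @export
cohens_kappa <- function(counts, se = c("simple", "fleiss"), conf_level = 0.95) {
  se <- match.arg(se)
  counts <- as.matrix(counts)
  n <- sum(counts)
  stopif_(n == 0L, "empty table")
  p <- counts / n
  po <- sum(diag(p))
  rowm <- rowSums(p); colm <- colSums(p)
  pe <- sum(rowm * colm)
  if (1 - pe < 1e-12) {
    return(list(kappa = NA_real_, se = NA_real_, ci = c(NA_real_, NA_real_)))
  }
  kappa <- (po - pe) / (1 - pe)
  z <- qnorm(1 - (1 - conf_level) / 2)
  se_val <- if (se == "simple") {
    sqrt(po * (1 - po) / (n * (1 - pe)^2))
  } else {
    A <- sum(diag(p) * (1 - (rowm + colm) * (1 - kappa))^2)
    # Fleiss-Cohen-Everitt: sum over i != j of p_ij (col_i + row_j)^2
    B <- (1 - kappa)^2 * sum(vapply(1:2, function(i) {
      sum(vapply(setdiff(1:2, i), function(j) {
        p[i, j] * (colm[i] + rowm[j])^2
      }, numeric(1)))
    }, numeric(1)))
    Cc <- (kappa - pe * (1 - kappa))^2
    sqrt((A + B - Cc) / n) / (1 - pe)
  }
  list(kappa = kappa, se = se_val,
       ci = c(kappa - z * se_val, kappa + z * se_val))
}

#' Pearson chi-square homogeneity test for an r x 2 table
#'
#' Raw-count chi-square of independence without continuity correction,
#' df = r - 1. Errors on zero expected counts.
#'
#' @param tab r x 2 count matrix.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
chi_square_homogeneity <- function(tab) {
  tab <- as.matrix(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stopif_(any(expected <= 0), "zero expected cell count")
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value))
}

#' Odds ratio of a 2x2 table with Woolf confidence interval
#'
#' OR = ad/bc; the CI is exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d)).
#' Tables with a zero cell get the Haldane-Anscombe +0.5 correction,
#' flagged in the result.
#'
#' @param counts 2x2 count matrix.
#' @param conf_level Confidence level.
#' @return List with `or`, `ci`, `haldane` (logical).
#' @export
odds_ratio <- function(counts, conf_level = 0.95) {
  m <- as.matrix(counts)
  stopifnot(all(dim(m) == c(2L, 2L)))
  haldane <- any(m == 0)
  if (haldane) m <- m + 0.5
  or <- (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
  z <- qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(sum(1 / m))
  list(or = or, ci = exp(log(or) + c(-z, z) * se), haldane = haldane)
}
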