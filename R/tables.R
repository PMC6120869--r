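# Published CBCS3 concordance tables, bundled as count data.

#' Published CBCS3 test-set concordance tables
#'
#' The 2x2 concordance count tables reported for the CBCS3 breast-cancer
#' image-analysis test set: image-analysis calls against pathologist tumor
#' grade (patient level), against IHC ER status (core level, with and
#' without grade-balanced training), against PAM50 Basal-like status,
#' ROR-PT class, and histologic subtype (core level), plus the agreement
#' between two pathologists on grade. Counts are stored with rows =
#' prediction/rater 1 and columns = reference/rater 2 in (negative,
#' positive) order: `a` = both negative, `b` = predicted negative /
#' reference positive, `c` = predicted positive / reference negative,
#' `d` = both positive. `positive_class` names the class used as the
#' sensitivity orientation in the corresponding published table.
#'
#' @return Data frame of count tables, one row per published 2x2 table.
#' @export
cbcs3_tables <- function() {
  path <- system.file("extdata", "cbcs3_concordance_tables.tsv",
                      package = "hemil", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
}

#' Recompute concordance statistics for the published CBCS3 tables
#'
#' Runs every bundled count table (see [cbcs3_tables()]) through the
#' concordance statistics: accuracy / sensitivity / specificity, percent
#' agreement, and Cohen's kappa with 95% CI. Percentages are rounded to
#' integers and kappa to 2 decimals, matching the reporting convention of
#' the source tables.
#'
#' @param rounded Round percentages to integers and kappa to 2 decimals.
#' @return Data frame: one row per table with the computed statistics.
#' @export
cbcs3_concordance <- function(rounded = TRUE) {
  tabs <- cbcs3_tables()
  stats <- lapply(seq_len(nrow(tabs)), function(i) {
    counts <- matrix(c(tabs$a[i], tabs$c[i], tabs$b[i], tabs$d[i]), 2L, 2L)
    r <- rates(counts)
    k <- cohens_kappa(counts)
    data.frame(
      table_id = tabs$table_id[i], task = tabs$task[i],
      stratum = tabs$stratum[i], n = sum(counts),
      accuracy = r[["accuracy"]], sensitivity = r[["sensitivity"]],
      specificity = r[["specificity"]],
      agreement = percent_agreement(counts),
      kappa = k$kappa, kappa_lo = k$ci[1], kappa_hi = k$ci[2]
    )
  })
  out <- do.call(rbind, stats)
  if (rounded) {
    for (col in c("accuracy", "sensitivity", "specificity", "agreement")) {
      out[[col]] <- round(out[[col]])
    }
    for (col in c("kappa", "kappa_lo", "kappa_hi")) {
      out[[col]] <- round(out[[col]], 2)
    }
  }
  out
}
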