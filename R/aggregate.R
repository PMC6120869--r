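# Bag-level aggregation: quantile signature, patient-level calibrated SVM,
# task-specific cut points.

#' Task-specific probability cut points
#'
#' Classification thresholds (strict greater-than) used on calibrated
#' patient/core probabilities: 0.80 for high grade, 0.50 for ER-positive,
#' 0.60 for Basal-like, 0.20 for high ROR-PT, 0.10 for lobular histology.
#'
#' @return Named numeric vector of cut points.
#' @export
default_cut_points <- function() {
  c(grade = 0.80, er = 0.50, basal = 0.60, ror = 0.20, histology = 0.10)
}

#' Quantile signature of region probabilities
#'
#' Summarizes the multiset of a bag's region probabilities by its empirical
#' quantile function (inverse CDF) sampled at 16 equally spaced levels.
#' Under the default `"inclusive"` convention the levels are i/15,
#' i = 0..15 (so the first and last values are the min and max) and values
#' between order statistics are linearly interpolated; `"midpoint"` uses
#' levels (i + 0.5)/16.
#'
#' @param probs Numeric vector of probabilities in \[0, 1\] (>= 1 value).
#' @param n_levels Number of quantile levels (16 by convention).
#' @param convention Level convention, `"inclusive"` or `"midpoint"`.
#' @return Numeric vector of `n_levels` non-decreasing values with
#'   attribute `levels`.
#' @export
quantile_signature <- function(probs, n_levels = 16L,
                               convention = c("inclusive", "midpoint")) {
  convention <- match.arg(convention)
  stopif_(length(probs) < 1L, "quantile signature of an empty bag")
  stopif_(any(!is.finite(probs)), "non-finite probabilities")
  lv <- if (convention == "inclusive") {
    (seq_len(n_levels) - 1) / (n_levels - 1)
  } else {
    (seq_len(n_levels) - 0.5) / n_levels
  }
  q <- quantile(probs, probs = lv, type = 7, names = FALSE)
  attr(q, "levels") <- lv
  q
}

#' Fit the patient-level calibrated classifier
#'
#' A linear SVM on 16-value quantile signatures with sigmoid (Platt)
#' calibration: patients are split into five class-stratified folds, the
#' SVM cost is selected from a small log grid by mean held-out AUC, a
#' logistic map is fit to the pooled held-out scores, and the final SVM is
#' refit on all training patients. Deterministic given `seed`.
#'
#' @param signatures Matrix (patients x 16) of quantile signatures.
#' @param labels Binary patient labels (0/1).
#' @param task Task name (one of [hemil_tasks()]), or `NULL`.
#' @param ensemble Optional `instance_ensemble` to embed so the returned
#'   pipeline can score raw feature bags.
#' @param weights Optional per-patient sample weights.
#' @param seed Integer seed for the calibration folds.
#' @param C_grid Candidate SVM cost values.
#' @param cut Classification cut point; defaults to the task's entry in
#'   [default_cut_points()] (0.5 when `task` is `NULL`).
#' @param convention Quantile-level convention used for signatures.
#' @return A `trained_pipeline`: patient scorer (`w`, `b`), `platt` map,
#'   `cut`, embedded `ensemble`, `task`, and the signature convention.
#' @export
fit_patient_model <- function(signatures, labels, task = NULL, ensemble = NULL,
                              weights = NULL, seed = 1L,
                              C_grid = c(0.01, 0.1, 1), cut = NULL,
                              convention = "inclusive") {
  X <- as.matrix(signatures)
  y <- as.integer(labels)
  stopif_(length(unique(y)) < 2L, "need both classes among training patients")
  n_folds <- 5L
  stopif_(min(table(y)) < n_folds,
          sprintf("need at least %d patients per class", n_folds))
  if (is.null(weights)) weights <- rep(1, length(y))
  fold <- stratified_folds_(y, n_folds, seed)
  cv <- lapply(C_grid, function(C) {
    scores <- numeric(length(y))
    for (k in seq_len(n_folds)) {
      tr <- fold != k
      fit <- wlsvm_fit_(X[tr, , drop = FALSE], y[tr], weights[tr], C = C)
      scores[!tr] <- wlsvm_score_(fit, X[!tr, , drop = FALSE])
    }
    list(auc = auc_(scores, y), scores = scores)
  })
  C_idx <- which.max(vapply(cv, `[[`, numeric(1), "auc"))
  C_sel <- C_grid[C_idx]
  platt <- platt_fit_(cv[[C_idx]]$scores, y)
  final <- wlsvm_fit_(X, y, weights, C = C_sel)
  if (is.null(cut)) {
    cut <- if (!is.null(task)) unname(default_cut_points()[task]) else 0.5
  }
  pipe <- list(task = task, ensemble = ensemble,
               w = final$w, b = final$b, platt = platt,
               C = C_sel, cut = cut, convention = convention, seed = seed)
  class(pipe) <- "trained_pipeline"
  pipe
}

# Region probabilities for a bag: either precomputed numerics or a
# feature_bag scored through the embedded instance ensemble.
region_probs_ <- function(pipeline, bag) {
  if (is.numeric(bag)) return(as.numeric(bag))
  stopifnot(inherits(bag, "feature_bag"))
  stopif_(is.null(pipeline$ensemble),
          "pipeline has no embedded instance ensemble; pass region probabilities")
  predict_instance_prob(pipeline$ensemble, bag)
}

# Signature -> calibrated probability.
score_signature_ <- function(pipeline, sig) {
  platt_predict_(pipeline$platt, sum(sig * pipeline$w) + pipeline$b)
}

#' Patient-level calibrated probability
#'
#' Pools the calibrated region probabilities from all of a patient's cores
#' into one quantile signature and scores it with the sigmoid-calibrated
#' patient SVM. A patient none of whose regions survived tissue filtering
#' is unscorable: the function warns and returns `NA` rather than silently
#' dropping the patient.
#'
#' @param pipeline A `trained_pipeline`.
#' @param bag A `feature_bag` with all the patient's regions, or a numeric
#'   vector of precomputed region probabilities.
#' @return Probability in \[0, 1\], or `NA` for an unscorable patient.
#' @export
predict_patient <- function(pipeline, bag) {
  probs <- region_probs_(pipeline, bag)
  if (length(probs) == 0L) {
    warning("unscorable patient: no regions survived filtering")
    return(NA_real_)
  }
  score_signature_(pipeline, quantile_signature(probs, convention = pipeline$convention))
}

#' Core-level calibrated probability
#'
#' As [predict_patient()] restricted to one core's regions. The default
#' method applies the patient-trained quantile+SVM scorer to the single
#' core's signature; `method = "mean_prob"` instead averages the core's
#' region probabilities.
#'
#' @inheritParams predict_patient
#' @param core_id Core to score (matched against the bag's entries); `NULL`
#'   uses all regions in `bag`.
#' @param method `"quantile_svm"` (default) or `"mean_prob"`.
#' @return Probability in \[0, 1\], or `NA` for an unscorable core.
#' @export
predict_core <- function(pipeline, bag, core_id = NULL,
                         method = c("quantile_svm", "mean_prob")) {
  method <- match.arg(method)
  if (inherits(bag, "feature_bag") && !is.null(core_id)) {
    keep <- bag$entries$core_id == core_id
    sub <- bag
    sub$entries <- bag$entries[keep, , drop = FALSE]
    sub$X <- bag$X[keep, , drop = FALSE]
    bag <- sub
  }
  probs <- region_probs_(pipeline, bag)
  if (length(probs) == 0L) {
    warning("unscorable core: no regions survived filtering")
    return(NA_real_)
  }
  if (method == "mean_prob") return(mean(probs))
  score_signature_(pipeline, quantile_signature(probs, convention = pipeline$convention))
}

#' Binary call from a calibrated probability
#'
#' Applies the task's cut point with a strict greater-than comparison and
#' returns the task's class label (e.g. probability 0.80 on the grade task
#' is still "low-intermediate"; 0.801 is "high").
#'
#' @param prob Probability (vectorized) in \[0, 1\].
#' @param task One of [hemil_tasks()].
#' @param cuts Named cut-point vector, defaults to [default_cut_points()].
#' @return Character vector of class labels.
#' @export
classify <- function(prob, task, cuts = default_cut_points()) {
  stopif_(!task %in% names(cuts), paste("unknown task:", task))
  stopif_(any(prob < 0 | prob > 1, na.rm = TRUE), "probabilities outside [0, 1]")
  lab <- task_labels_(task)
  out <- ifelse(prob > cuts[[task]], lab[["pos"]], lab[["neg"]])
  out[is.na(prob)] <- NA_character_
  out
}

#' Select a probability cut point
#'
#' Grid search over the observed probabilities, maximizing Youden's J
#' (sensitivity + specificity - 1) or accuracy of the strict greater-than
#' rule; ties resolve to the lowest candidate threshold.
#'
#' @param probs Predicted probabilities.
#' @param truths Binary reference labels (0/1).
#' @param criterion `"youden"` or `"accuracy"`.
#' @return The selected cut value.
#' @export
select_cut_point <- function(probs, truths, criterion = c("youden", "accuracy")) {
  criterion <- match.arg(criterion)
  truths <- as.integer(truths)
  stopif_(length(unique(truths)) < 2L, "both classes required to select a cut point")
  cand <- sort(unique(c(0, probs)))
  npos <- sum(truths == 1L); nneg <- sum(truths == 0L)
  score <- vapply(cand, function(cut) {
    call <- as.integer(probs > cut)
    sens <- sum(call == 1L & truths == 1L) / npos
    spec <- sum(call == 0L & truths == 0L) / nneg
    if (criterion == "youden") sens + spec - 1 else mean(call == truths)
  }, numeric(1))
  cand[which(score >= max(score) - 1e-12)[1]]
}
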