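# Region-level (instance) model: five-member cross-validated ensemble of
# isotonically calibrated linear SVMs.

#' Per-sample weights for balanced training
#'
#' Computes weights inversely proportional to cell counts so every cell's
#' total weight is equal, rescaled so the mean weight is 1. Under
#' `uniform_class` the cells are the two classes; under `grade_by_class`
#' they are the four grade-bin x class combinations (low-intermediate /
#' high crossed with the task's two classes), the scheme used to reduce the
#' leverage of grade when predicting ER status or intrinsic subtype.
#'
#' @param class Per-sample class labels (binary, any two values).
#' @param grade_bin Per-sample grade bins (required for `grade_by_class`).
#' @param scheme `"uniform_class"` or `"grade_by_class"`.
#' @return Numeric weights, mean 1; cell totals are equal across cells.
#' @export
compute_sample_weights <- function(class, grade_bin = NULL,
                                   scheme = c("uniform_class", "grade_by_class")) {
  scheme <- match.arg(scheme)
  cell <- if (scheme == "grade_by_class") {
    stopif_(is.null(grade_bin), "grade_by_class weighting requires grade_bin")
    stopif_(length(grade_bin) != length(class),
            "class and grade_bin lengths differ")
    interaction(grade_bin, class, drop = FALSE, sep = " / ")
  } else {
    factor(class)
  }
  counts <- table(cell)
  empty <- names(counts)[counts == 0L]
  stopif_(length(empty) > 0L,
          paste0("empty weighting cell(s): ", paste(empty, collapse = ", ")))
  K <- length(class) / length(counts)
  w <- as.numeric(K / counts[as.character(cell)])
  w
}

# Stack a list of feature bags into instance-level matrices.
stack_bags_ <- function(bags, labels, grade_bins = NULL) {
  stopifnot(length(bags) == length(labels))
  nreg <- vapply(bags, function(b) nrow(b$X), integer(1))
  X <- do.call(rbind, lapply(bags, function(b) b$X))
  list(
    X = X,
    y = rep(as.integer(labels), nreg),
    patient = rep(seq_along(bags), nreg),
    grade_bin = if (is.null(grade_bins)) NULL else rep(grade_bins, nreg)
  )
}

#' Fit the five-member calibrated instance ensemble
#'
#' Training patients are partitioned into five class-stratified folds (all
#' regions of a patient share a fold, preventing leakage between fitting
#' and calibration). Member k is a linear SVM fit with per-sample weights
#' on the regions of folds != k, calibrated by isotonic regression on fold
#' k's scores against the broadcast patient labels. The SVM cost C is
#' selected once from a small log grid by mean calibration-fold AUC.
#' Features are z-scored with statistics of the full training set
#' (zero-variance dimensions left unscaled); the statistics are stored in
#' the ensemble. Deterministic given `seed`.
#'
#' @param bags List of `feature_bag`s (training patients).
#' @param labels Binary patient labels (0/1), one per bag; broadcast to
#'   every region of the bag.
#' @param grade_bins Optional per-patient grade bins for
#'   `scheme = "grade_by_class"`.
#' @param scheme Sample-weighting scheme, see [compute_sample_weights()].
#' @param seed Integer seed controlling the fold shuffle.
#' @param C_grid Candidate SVM cost values.
#' @param n_members Ensemble size (folds), 5 by convention.
#' @return An `instance_ensemble`: members (linear weights + isotonic
#'   maps), standardization statistics, selected `C`, fold assignment.
#' @export
fit_instance_ensemble <- function(bags, labels, grade_bins = NULL,
                                  scheme = c("uniform_class", "grade_by_class"),
                                  seed = 1L, C_grid = c(0.01, 0.1, 1),
                                  n_members = 5L) {
  scheme <- match.arg(scheme)
  labels <- as.integer(labels)
  stopif_(length(unique(labels)) < 2L, "need both classes among training patients")
  stopif_(min(table(labels)) < n_members,
          sprintf("need at least %d patients per class for %d patient-level folds",
                  n_members, n_members))
  st <- stack_bags_(bags, labels, grade_bins)
  mu <- colMeans(st$X)
  sdv <- apply(st$X, 2L, sd)
  sdv[sdv < 1e-12] <- 1
  Xs <- sweep(sweep(st$X, 2L, mu, "-"), 2L, sdv, "/")
  w_inst <- if (scheme == "grade_by_class") {
    compute_sample_weights(st$y, st$grade_bin, scheme)
  } else {
    compute_sample_weights(st$y, scheme = scheme)
  }
  fold_patient <- stratified_folds_(labels, n_members, seed)
  fold_inst <- fold_patient[st$patient]
  for (k in seq_len(n_members)) {
    if (length(unique(st$y[fold_inst == k])) < 2L) {
      stop("calibration fold ", k, " contains a single class; ",
           "re-seed or provide more patients", call. = FALSE)
    }
  }
  member_fits <- function(C) {
    lapply(seq_len(n_members), function(k) {
      tr <- fold_inst != k
      wlsvm_fit_(Xs[tr, , drop = FALSE], st$y[tr], w_inst[tr], C = C)
    })
  }
  cv_auc <- vapply(C_grid, function(C) {
    fits <- member_fits(C)
    mean(vapply(seq_len(n_members), function(k) {
      ca <- fold_inst == k
      auc_(wlsvm_score_(fits[[k]], Xs[ca, , drop = FALSE]), st$y[ca])
    }, numeric(1)))
  }, numeric(1))
  C_sel <- C_grid[which.max(cv_auc)]
  fits <- member_fits(C_sel)
  members <- lapply(seq_len(n_members), function(k) {
    ca <- fold_inst == k
    scores <- wlsvm_score_(fits[[k]], Xs[ca, , drop = FALSE])
    list(w = fits[[k]]$w, b = fits[[k]]$b,
         iso = isotonic_fit_(scores, st$y[ca]))
  })
  ens <- list(members = members,
              standardization = list(mu = mu, sd = sdv),
              C = C_sel, cv_auc = setNames(cv_auc, C_grid),
              scheme = scheme, seed = seed, d = ncol(st$X),
              fold = fold_patient)
  class(ens) <- "instance_ensemble"
  ens
}

#' Calibrated region probabilities from the ensemble
#'
#' The probability of each region is the arithmetic mean of the five
#' members' isotonically calibrated outputs.
#'
#' @param ensemble An `instance_ensemble`.
#' @param bag A `feature_bag` (or plain feature matrix).
#' @return Numeric vector of per-region probabilities in \[0, 1\].
#' @export
predict_instance_prob <- function(ensemble, bag) {
  X <- if (inherits(bag, "feature_bag")) bag$X else as.matrix(bag)
  stopif_(ncol(X) != ensemble$d,
          sprintf("feature dimension %d does not match ensemble dimension %d",
                  ncol(X), ensemble$d))
  Xs <- sweep(sweep(X, 2L, ensemble$standardization$mu, "-"),
              2L, ensemble$standardization$sd, "/")
  P <- vapply(ensemble$members, function(m) {
    isotonic_predict_(m$iso, drop(Xs %*% m$w) + m$b)
  }, numeric(nrow(Xs)))
  if (nrow(Xs) == 1L) P <- matrix(P, nrow = 1L)
  rowMeans(P)
}
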