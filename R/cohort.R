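#' Prediction tasks
#'
#' The five binary patient-level prediction tasks supported by the pipeline.
#' Each task has a designated positive class: `grade` (high vs
#' low-intermediate), `er` (ER-positive vs negative), `basal` (Basal-like vs
#' non-Basal-like PAM50 subtype), `ror` (high vs low-medium ROR-PT), and
#' `histology` (lobular vs ductal).
#'
#' @return Character vector of task names.
#' @export
hemil_tasks <- function() c("grade", "er", "basal", "ror", "histology")

# Positive/negative display labels per task.
task_labels_ <- function(task) {
  switch(task,
    grade     = c(neg = "low-intermediate", pos = "high"),
    er        = c(neg = "negative",         pos = "positive"),
    basal     = c(neg = "non-basal",        pos = "basal"),
    ror       = c(neg = "low-med",          pos = "high"),
    histology = c(neg = "ductal",           pos = "lobular"),
    stop("unknown task: ", task)
  )
}

# ROR-PT continuous score threshold dichotomizing low-med vs high.
ROR_CUTOFF <- 64.7

#' Configuration for a synthetic TMA cohort
#'
#' Bundles the parameters of the synthetic cohort generator. Defaults
#' reproduce the marginal label frequencies of the CBCS3 training set
#' (34.2% high grade, 75.1% ER-positive, ~21% Basal-like, ~10% lobular)
#' and the study design (1-4 cores per patient, 2/3 train split).
#'
#' @param n_patients Number of patients to simulate.
#' @param marginals Named list of class frequencies: `grade_high`,
#'   `er_positive`, `lobular`. PAM50 subtype is drawn conditionally on ER
#'   status (see `subtype_given_er`); ROR-PT is drawn uniform on 0-100 and
#'   dichotomized at 64.7.
#' @param grade_er_association Odds ratio odds(ER+ | high grade) /
#'   odds(ER+ | low-intermediate grade). 1 = independence; values < 1 make
#'   high-grade tumors ER-negative-enriched as observed in breast cancer.
#' @param subtype_given_er Conditional probability table (2 x 5 matrix,
#'   rows `negative`/`positive`, columns LumA/LumB/HER2/Basal/Normal).
#' @param heterogeneity Fraction of regions in a bag drawn from the
#'   opposite class's feature distribution (intra-tumor heterogeneity).
#' @param effect_size Standardized mean separation (Cohen's d per the
#'   discriminant axis) between class-conditional feature distributions.
#' @param grade_effect Additional mean offset along a fixed grade axis,
#'   planted in every task's bags so grade acts as a confounding image
#'   feature (0 disables).
#' @param feature_dim Feature dimension d of synthesized region vectors.
#' @param regions_per_core Regions simulated per core.
#' @param train_fraction Fraction of patients assigned to the training
#'   split.
#' @param seed Integer seed; all generator draws are deterministic in it.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 300,
                          marginals = list(grade_high = 0.342,
                                           er_positive = 0.751,
                                           lobular = 0.10),
                          grade_er_association = 0.15,
                          subtype_given_er = NULL,
                          heterogeneity = 0.1,
                          effect_size = 3,
                          grade_effect = 1,
                          feature_dim = 512L,
                          regions_per_core = 16L,
                          train_fraction = 2 / 3,
                          seed = 1L) {
  if (is.null(subtype_given_er)) {
    subtype_given_er <- rbind(
      negative = c(LumA = 0.03, LumB = 0.06, HER2 = 0.13, Basal = 0.72, Normal = 0.06),
      positive = c(LumA = 0.60, LumB = 0.24, HER2 = 0.08, Basal = 0.03, Normal = 0.05)
    )
  }
  cfg <- list(
    n_patients = as.integer(n_patients),
    marginals = marginals,
    grade_er_association = grade_er_association,
    subtype_given_er = subtype_given_er,
    heterogeneity = heterogeneity,
    effect_size = effect_size,
    grade_effect = grade_effect,
    feature_dim = as.integer(feature_dim),
    regions_per_core = as.integer(regions_per_core),
    train_fraction = train_fraction,
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  freqs <- unlist(cfg$marginals)
  stopif_(any(freqs < 0 | freqs > 1), "all marginal frequencies must lie in [0, 1]")
  stopif_(cfg$heterogeneity < 0 || cfg$heterogeneity > 1,
          "heterogeneity must lie in [0, 1]")
  stopif_(cfg$effect_size < 0, "effect_size must be >= 0")
  stopif_(cfg$grade_er_association < 0, "grade_er_association must be >= 0")
  stopif_(cfg$n_patients < 4L, "n_patients too small to populate classes")
  stopif_(cfg$train_fraction <= 0 || cfg$train_fraction >= 1,
          "train_fraction must lie in (0, 1)")
  stopif_(any(abs(rowSums(cfg$subtype_given_er) - 1) > 1e-8),
          "subtype_given_er rows must sum to 1")
  invisible(cfg)
}

# Solve P(ER+ | low-int) and P(ER+ | high) matching the overall marginal p
# and the odds ratio `or`, given P(high) = pi_high.
er_given_grade_ <- function(p, pi_high, or) {
  if (abs(or - 1) < 1e-12) return(c(neg = p, pos = p))
  f <- function(p0) {
    o0 <- p0 / (1 - p0)
    p1 <- or * o0 / (1 + or * o0)
    (1 - pi_high) * p0 + pi_high * p1 - p
  }
  lo <- 1e-9; hi <- 1 - 1e-9
  stopif_(f(lo) > 0 || f(hi) < 0,
          "no conditional ER rates satisfy the requested marginal and odds ratio")
  p0 <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  o0 <- p0 / (1 - p0)
  p1 <- or * o0 / (1 + or * o0)
  c(neg = p0, pos = p1)  # neg = low-int grade, pos = high grade
}

#' Generate a synthetic patient cohort
#'
#' Draws patient-level labels for all five tasks with the marginal
#' structure configured in `config`: three-level grade (high frequency per
#' `marginals$grade_high`; low vs intermediate split 40/60 within the
#' low-intermediate stratum), ER status correlated with grade through
#' `grade_er_association`, PAM50 subtype conditional on ER, histology,
#' continuous ROR-PT (uniform 0-100, dichotomized at 64.7), 1-4 cores per
#' patient, and a fixed-size random train/test split.
#'
#' @param config A [cohort_config()].
#' @return A `data.frame` (class `hemil_cohort`) with one row per patient:
#'   `patient_id`, `grade`, `grade_bin`, `er`, `subtype`, `histology`,
#'   `ror_continuous`, `ror_class`, `n_cores`, `split`.
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  n <- config$n_patients
  cohort <- with_seed_(config$seed, {
    grade_bin <- rbinom(n, 1L, config$marginals$grade_high)
    low_split <- rbinom(n, 1L, 0.6)   # intermediate share within low-int
    grade <- ifelse(grade_bin == 1L, "high",
                    ifelse(low_split == 1L, "intermediate", "low"))
    p_er <- er_given_grade_(config$marginals$er_positive,
                            config$marginals$grade_high,
                            config$grade_er_association)
    er <- ifelse(runif(n) < ifelse(grade_bin == 1L, p_er["pos"], p_er["neg"]),
                 "positive", "negative")
    subtype <- vapply(er, function(e) {
      sample(colnames(config$subtype_given_er), 1L,
             prob = config$subtype_given_er[e, ])
    }, character(1), USE.NAMES = FALSE)
    histology <- ifelse(runif(n) < config$marginals$lobular, "lobular", "ductal")
    ror_continuous <- runif(n, 0, 100)
    ror_class <- ifelse(ror_continuous > ROR_CUTOFF, "high", "low_med")
    n_cores <- sample(1:4, n, replace = TRUE)
    split <- rep("test", n)
    split[sample.int(n, round(n * config$train_fraction))] <- "train"
    data.frame(
      patient_id = sprintf("P%04d", seq_len(n)),
      grade = grade,
      grade_bin = ifelse(grade_bin == 1L, "high", "low-intermediate"),
      er = er,
      subtype = subtype,
      histology = histology,
      ror_continuous = ror_continuous,
      ror_class = ror_class,
      n_cores = n_cores,
      split = split,
      stringsAsFactors = FALSE
    )
  })
  for (task in hemil_tasks()) {
    y <- task_truth(cohort, task)
    tab <- table(factor(y, levels = 0:1))
    if (any(tab < 2L)) {
      lab <- task_labels_(task)[if (tab[1] < 2L) "neg" else "pos"]
      stop(sprintf("task '%s': fewer than 2 patients in class '%s'; increase n_patients",
                   task, lab), call. = FALSE)
    }
  }
  attr(cohort, "config") <- config
  class(cohort) <- c("hemil_cohort", "data.frame")
  cohort
}

#' Binary ground-truth labels for a task
#'
#' @param cohort A cohort data frame from [generate_cohort()] (or any data
#'   frame with the same label columns).
#' @param task One of [hemil_tasks()].
#' @return Integer vector, 1 = positive class of the task.
#' @export
task_truth <- function(cohort, task) {
  switch(task,
    grade     = as.integer(cohort$grade == "high"),
    er        = as.integer(cohort$er == "positive"),
    basal     = as.integer(cohort$subtype == "Basal"),
    ror       = as.integer(cohort$ror_class == "high"),
    histology = as.integer(cohort$histology == "lobular"),
    stop("unknown task: ", task)
  )
}

#' Planted discriminant directions of the feature generator
#'
#' Unit vectors (one per task, plus the shared grade axis) along which the
#' generator offsets class-conditional feature means. Deterministic in the
#' config seed and feature dimension; exposed so tests can use the
#' generator's own geometry as an oracle.
#'
#' @param config A [cohort_config()].
#' @return Matrix `feature_dim` x 6 with columns `grade, er, basal, ror,
#'   histology, grade_axis` (the `grade` task direction equals
#'   `grade_axis`).
#' @export
task_directions <- function(config) {
  d <- config$feature_dim
  U <- with_seed_(derive_seed_(config$seed, "directions"), {
    matrix(rnorm(d * 5L), d, 5L)
  })
  U <- sweep(U, 2L, sqrt(colSums(U^2)), "/")
  colnames(U) <- c("grade", "er", "basal", "ror", "histology")
  cbind(U, grade_axis = U[, "grade"])
}

#' Synthesize a feature bag for one patient
#'
#' Draws one pooled feature vector per region from the class-conditional
#' distribution of the patient's task label: spherical unit-variance
#' Gaussians whose means sit at +/- `effect_size`/2 along the task's planted
#' unit direction, plus (for tasks other than grade) a +/- `grade_effect`/2
#' offset along the shared grade axis so tumor grade acts as a confounding
#' feature. With probability `heterogeneity` a region is drawn from the
#' opposite class instead; the realized per-region class is kept in the
#' returned bag as generator ground truth.
#'
#' @param record A single-row patient record (one row of a cohort).
#' @param task One of [hemil_tasks()].
#' @param config The [cohort_config()] used to generate the cohort.
#' @return A `feature_bag`: list with `patient_id`, `entries` (data frame of
#'   `core_id`, `region_row`, `region_col`), feature matrix `X`
#'   (regions x d), `instance_class` (realized 0/1 region classes), `d`.
#' @export
synthesize_feature_bag <- function(record, task, config) {
  stopif_(!task %in% hemil_tasks(), paste("unknown task:", task))
  stopif_(config$regions_per_core < 1L,
          "regions_per_core must be >= 1 (empty bag)")
  d <- config$feature_dim
  U <- task_directions(config)
  u_task <- U[, task]
  u_grade <- U[, "grade_axis"]
  y <- task_truth(record, task)
  g <- as.integer(record$grade_bin == "high")
  n_regions <- record$n_cores * config$regions_per_core
  seed <- derive_seed_(config$seed, paste0("bag:", record$patient_id, ":", task))
  bag <- with_seed_(seed, {
    flip <- rbinom(n_regions, 1L, config$heterogeneity)
    y_inst <- ifelse(flip == 1L, 1L - y, y)
    X <- matrix(rnorm(n_regions * d), n_regions, d)
    X <- X + tcrossprod(config$effect_size * (y_inst - 0.5), u_task)
    if (task != "grade" && config$grade_effect != 0) {
      X <- X + tcrossprod(rep(config$grade_effect * (g - 0.5), n_regions), u_grade)
    }
    k <- config$regions_per_core
    idx <- seq_len(n_regions) - 1L
    within <- idx %% k
    list(
      patient_id = record$patient_id,
      entries = data.frame(
        core_id = idx %/% k + 1L,
        region_row = (within %/% 4L) * 400L,
        region_col = (within %% 4L) * 400L
      ),
      X = X,
      instance_class = y_inst,
      d = d
    )
  })
  class(bag) <- "feature_bag"
  bag
}

#' Synthesize feature bags for a whole cohort
#'
#' @inheritParams synthesize_feature_bag
#' @param cohort A cohort from [generate_cohort()].
#' @return Named list of [synthesize_feature_bag()] results, one per patient.
#' @export
synthesize_cohort_bags <- function(cohort, task, config = attr(cohort, "config")) {
  bags <- lapply(seq_len(nrow(cohort)), function(i) {
    synthesize_feature_bag(cohort[i, ], task, config)
  })
  names(bags) <- cohort$patient_id
  bags
}

#' Write / read a cohort label table
#'
#' Tab-separated serialization of the patient label table.
#'
#' @param cohort Cohort data frame.
#' @param path Output TSV path.
#' @return `path` invisibly, or (for the reader) the cohort data frame.
#' @export
write_label_table <- function(cohort, path) {
  write.table(as.data.frame(cohort), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_label_table
#' @export
read_label_table <- function(path) {
  cohort <- read.delim(path, stringsAsFactors = FALSE)
  class(cohort) <- c("hemil_cohort", "data.frame")
  cohort
}

#' Write / read feature bags in columnar TSV form
#'
#' One row per region: `patient_id`, `core_id`, `region_row`, `region_col`,
#' `f0` ... `f{d-1}`.
#'
#' @param bags Named list of `feature_bag` objects.
#' @param path TSV path.
#' @return `path` invisibly, or (for the reader) the list of bags.
#' @export
write_feature_bags <- function(bags, path) {
  rows <- lapply(bags, function(b) {
    Xd <- as.data.frame(b$X)
    names(Xd) <- paste0("f", seq_len(ncol(b$X)) - 1L)
    cbind(data.frame(patient_id = b$patient_id), b$entries, Xd)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_bags
#' @export
read_feature_bags <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  fcols <- grep("^f[0-9]+$", names(df), value = TRUE)
  fcols <- fcols[order(as.integer(sub("^f", "", fcols)))]
  bags <- lapply(split(df, df$patient_id), function(g) {
    b <- list(
      patient_id = g$patient_id[1],
      entries = g[, c("core_id", "region_row", "region_col")],
      X = as.matrix(g[, fcols, drop = FALSE]),
      instance_class = NULL,
      d = length(fcols)
    )
    rownames(b$entries) <- NULL
    dimnames(b$X) <- NULL
    class(b) <- "feature_bag"
    b
  })
  bags[unique(df$patient_id)]
}
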