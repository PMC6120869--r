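---
title: "Weakly supervised classification of H&E tissue microarray images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weakly supervised classification of H&E tissue microarray images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Breast tumors on a tissue microarray (TMA) are imaged as 1-mm circular
H&E-stained cores, 1-4 cores per patient, at 20x magnification (roughly
2500 x 2500 px per core). Labels of clinical interest — Nottingham grade
(binarized low-intermediate vs high), ER status, PAM50 Basal-like vs
non-Basal-like subtype, dichotomized ROR-PT risk of recurrence, and
ductal vs lobular histology — exist only at the patient level. Tissue
within a single core is heterogeneous, so broadcasting the patient label
to every image region produces noisy region labels. This is the classic
multiple instance learning (MIL) setting: bags (patients) are labeled,
instances (800 x 800 px regions) are not.

`hemil` implements the full pipeline:

1. **Stain normalization.** Images are mapped to optical density (OD) by
   Beer-Lambert ($\mathrm{OD} = -\log_{10} I$), the two dominant stain
   vectors are estimated Macenko-style (extreme angles at the 1st/99th
   percentile in the top-2 singular plane of the OD cloud of
   above-threshold pixels), per-pixel hematoxylin/eosin concentrations
   are unmixed by least squares and clamped at zero, rescaled so each
   stain's 99th-percentile concentration matches the reference profile,
   and reconstructed with the reference stain vectors. Glass maps back to
   near-white; a blank image short-circuits to a `no_tissue` flag.
2. **Tissue detection and tiling.** A pixel is tissue iff its total OD
   exceeds 0.15; connected components under 64 px are removed. Candidate
   regions are 800 x 800 px at every multiple of the stride that fits in
   the image (0-based, row-major), kept iff mean tissue coverage is at
   least 0.5. Stride defaults: 800 (non-overlapping) for training, 400
   (overlapping) at test time — overlap is only specified for prediction,
   and the same 50% tissue rule is applied in both phases.
3. **Region features.** A pluggable extractor produces a spatial grid of
   d-dimensional vectors at 1/8 image resolution, and each kept region's
   vector is the mean of the grid cells its footprint covers (offsets are
   divided by 8, flooring at the start and ceiling at the end, so every
   contributing cell counts). The default backend is a deterministic
   filter bank (per-cell stain means and dispersions, gradient-magnitude
   energy, difference-of-gaussian blob responses at sigma = 1, 2, 4, and
   RGB means, zero-padded to d); a `cnn_intermediate` backend mirroring
   intermediate convolutional activations of a transferred network is
   specified but errors with instructions to use the filter bank unless
   pretrained weights and a runtime are present. Downstream stages are
   backend-agnostic; features are z-scored with training-set statistics
   before any SVM because linear SVMs are scale-sensitive.
4. **Instance model.** Training patients are split into five
   class-stratified folds *by patient*, so all regions of a patient share
   a fold and no patient leaks between fitting and calibration. Member k
   is a linear SVM fit on folds ≠ k (with per-sample weights, below) and
   calibrated by isotonic regression — a piecewise-constant non-decreasing
   map from score to [0, 1], fit by pooled-adjacent-violators with average
   pooling of ties — on fold k. A region's probability is the mean of the
   five calibrated outputs.
5. **Aggregation.** A bag's region probabilities are summarized by the
   empirical quantile function sampled at 16 equally spaced levels
   $i/15$, $i = 0..15$ (linear interpolation between order statistics;
   the first and last values are the min and max). A second linear SVM on
   these 16-value signatures, with Platt (sigmoid) calibration fit on
   pooled 5-fold held-out scores, yields the patient probability. Binary
   calls use strict greater-than cut points: 0.80 (high grade), 0.50
   (ER+), 0.60 (Basal-like), 0.20 (high ROR-PT), 0.10 (lobular).
   Core-level predictions reuse the patient-trained scorer on single-core
   signatures (the alternative — averaging region probabilities — is
   available as `method = "mean_prob"`).
6. **Evaluation.** 2x2 concordance tables (rows = prediction, columns =
   reference, negative class first) with accuracy/sensitivity/specificity
   in percent, percent agreement, Cohen's kappa
   $\kappa = (p_o - p_e)/(1 - p_e)$ with the simple asymptotic CI
   $\kappa \pm 1.96\sqrt{p_o(1-p_o)/(n(1-p_e)^2)}$, Pearson chi-square
   homogeneity, and odds ratios with Woolf intervals (Haldane +0.5 on
   zero cells, flagged).

## Sample weighting

With `scheme = "grade_by_class"` each sample is weighted inversely to the
size of its grade-bin x class cell (low-intermediate/high crossed with
the task's two classes), scaled so the mean weight is 1; each nonempty
cell then carries equal total weight. This reduces the leverage of tumor
grade when predicting ER status or subtype, at a documented cost in raw
accuracy. Because the four weights differ *within* a class, class-weight
interfaces of off-the-shelf SVMs cannot express the scheme; the package
therefore fits the primal weighted squared-hinge linear SVM

$$\tfrac12\lVert w\rVert^2 + C\,M\,\frac{\sum_i v_i\,\max(0, 1 - s_i(x_i^\top w + b))^2}{\sum_i v_i}$$

by L-BFGS-B with analytic gradients (deterministic; zero
initialization). The data term is a weighted mean times a fixed
multiplier M = 256, so the fit is invariant to duplicating the training
set and the cost grid C ∈ {0.01, 0.1, 1} keeps its meaning at any sample
size; C is selected once per ensemble by mean calibration-fold AUC (ties
go to the smallest C). A unit test cross-checks the resulting
discriminant direction against an independent SVM implementation
(`e1071`) in the uniform-weight case.

## The synthetic cohort generator

CBCS3 images are available on request only, so the package ships a
generator that reproduces the *statistical structure* of the study and
makes every stage testable offline. Its defaults are fixed study
conditions, not tuning knobs:

- Label marginals follow the training-set frequency table: 34.2% high
  grade (low vs intermediate split 40/60 within the low-intermediate
  stratum), 75.1% ER-positive, 10% lobular. ER is drawn conditionally on
  grade to honor a configurable odds ratio (default 0.15: high-grade
  tumors are strongly ER-negative-enriched, as observed in this
  population); PAM50 subtype is drawn conditionally on ER (Basal-like
  mass concentrated in ER-negative patients), reproducing the structure
  that makes Luminal B the hard case. ROR-PT is uniform on 0-100 and
  dichotomized at 64.7 — only the cutoff is published. Cores per patient
  are uniform on {1, 2, 3, 4} (the study states the range, not the
  distribution); the train fraction is 2/3 as a fixed-size random
  partition.
- Region feature vectors are spherical unit-variance Gaussians whose
  means sit at ±effect_size/2 along a task-specific random unit
  direction — the simplest family with a closed-form Bayes oracle
  (instance AUC $\Phi(\text{effect\_size}/\sqrt2)$, ≈ 0.983 at the
  default effect size 3, the standardized mean separation in Cohen's-d
  convention). With probability `heterogeneity` (default 0.1) a region is
  drawn from the opposite class, emulating intra-tumor heterogeneity; the
  realized region class is kept as ground truth for tests. For tasks
  other than grade a second offset of ±`grade_effect`/2 along a shared
  grade axis plants grade as a confounding image feature, which is what
  makes the grade-weighting effect measurable.
- `regions_per_core` defaults to 16, the typical yield of a 2500 px core
  tiled at stride 400 after the 50% tissue rule; `feature_dim` defaults
  to 512 to match the CNN feature width.
- Procedural core images are circular tissue discs on near-white glass,
  built in concentration space (smooth eosin stroma, nucleus-like
  hematoxylin blobs whose density/size/amplitude depend on grade, a few
  lumen-like holes) and rendered through the same Beer-Lambert model the
  normalizer inverts, so stain unmixing can be validated against the
  generator's own concentration maps.

What the generator does *not* emulate: realistic nuclear morphology,
spatial correlation of heterogeneity within a core, staining artifacts
(folds, blur, fading gradients), class-conditional distributions that are
non-Gaussian or non-linear in feature space, and survey sampling weights.
Passing recovery tests therefore demonstrates that the pipeline's
machinery is correct and calibrated under its own assumptions — not that
the reported CBCS3 accuracies would be reproduced on real images.

## Numerical choices and degenerate inputs

- Quantile levels include both extremes (`i/15`); the midpoint
  alternative `(i + 0.5)/16` is a config switch. Duplicating every
  region changes the signature not at all when the region count is
  1 (mod 15) — interpolation positions then stay inside replicated
  order-statistic blocks — and by O(range/n) otherwise.
- Isotonic maps clamp out-of-range scores to the nearest plateau;
  sigmoid calibration falls back to the identity-slope map if the
  logistic fit does not produce finite coefficients.
- Cut-point selection maximizes Youden's J over observed probabilities;
  ties resolve to the lowest candidate.
- Zero-variance feature dimensions are left unscaled by the z-scoring.
- Unscorable patients/cores (no regions survive tissue filtering) yield
  `NA` with a warning, never silent omission; empty weighting cells and
  single-class inputs fail with named diagnostics.
- Kappa is `NA` when the margins are degenerate ($p_e = 1$); a zero
  reference margin makes sensitivity `NA` (reported N/A). The
  Fleiss-Cohen-Everitt kappa variance is available behind
  `se = "fleiss"`; the default simple asymptotic form is the one that
  reproduces the published ER kappa CI, and stratum-level published CIs
  that match no standard formula are not asserted.

## Problem sizes used by the checks

The test suite exercises cohorts of 20-150 patients at feature
dimensions 5-64; the end-to-end benchmark (also run by
`scripts/acceptance.R`) uses the study-like conditions of 200 training
and 100 test patients at the default feature dimension 512, effect size
3, heterogeneity 0.1, with a single-permutation shuffled-label control
on the ER task. The image-path integration test renders 256 px
procedural cores; tiling and normalization contracts are checked at full
2500 px geometry where cheap (masks, closed-form counts).

## Known limitations

- The CNN backend is an interface contract only; without pretrained
  weights the filter bank is the operative extractor, and its features
  are far weaker than transferred CNN activations on real tissue.
- The shuffled-label control of a CV-calibrated pipeline concentrates
  *below* the majority rate rather than at it: a fixed permutation keeps
  a global chance correlation with the dominant class axis that
  cross-validation cannot remove, producing non-constant predictions.
  The control therefore demonstrates "no fabricated signal" (it never
  significantly beats the majority rate), not "majority-rate accuracy".
- Core-level training is not separately specified; core predictions
  reuse the patient-trained scorer.
- Multiclass PAM50 subtyping is out of scope; all tasks are binary.

## A minimal run

```{r example}
library(hemil)
cfg <- run_config(n_patients = 60, tasks = c("grade", "er"),
                  weighting = list(er = "grade_by_class"),
                  cohort = list(feature_dim = 32L, regions_per_core = 8L),
                  seed = 1, outdir = "hemil_run")
run <- run_pipeline(cfg)
run$results$er$metrics          # confusion summary on the test split
cbcs3_concordance()             # published-table statistics, recomputed
```
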