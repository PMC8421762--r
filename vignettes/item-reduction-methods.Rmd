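---
title: "How itemreduce decides how few diagnostic items are enough"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How itemreduce decides how few diagnostic items are enough}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itemreduce)
```

## The problem

Gold-standard autism assessment combines a semi-structured behaviour
observation (ADOS, items coded 0--3 for increasing severity plus special
codes 7/8) with a structured caregiver interview (ADI-R, 93 items of which
37 enter the diagnostic algorithm across domains A--C). Both are long, and
clinical capacity is scarce. `itemreduce` implements a data-driven answer
to the question *which items, and how many, carry the diagnostic signal*:
a feature-ranking and nested-model-selection procedure built around random
forests, with a binary best-estimate clinical label (ASD vs non-ASD) as
the reference. The positive class is ASD throughout, so "sensitivity"
always means ASD detection.

## The procedure

Four consecutive steps, after preparation:

0. **Preparation.** Special codes 7/8 are remapped to 0 and severity code
   3 collapsed into 2 (`recode_item_codes()`); ADI-R items are restricted
   to the 37 algorithm items outside domain D, while all ADOS items stay
   (`select_algorithm_items()`). A stratified 25% of subjects is held out
   as a validation set the model-building never sees
   (`train_validation_split()`). Missing item codes are *kept as valid
   values* — they are encoded as a sentinel category (−1) so that no
   subject is dropped.

1. **Importance ranking** (`run_cv_importance()`,
   `aggregate_ranking()`). A class-stratified 20-fold cross-validation is
   laid over the training partition; each of 20 runs trains a 400-tree
   random forest on 95% of the training data and measures, on the held-out
   5% fold, the *mean decrease in accuracy* when one item's column is
   permuted. Measuring importance on held-out subjects rather than
   in-sample avoids optimistic bias; we average over a small number of
   permutations per item (default 5) because a 5% fold makes accuracy a
   coarse-grained quantity. Every run yields a full importance hierarchy;
   items are ordered by their mean rank across runs, ties broken by mean
   importance and then item id so the ordering is total and
   deterministic. An alternative scheme in which every run draws its own
   fold partition is available (`independent_runs = TRUE`); the default
   identifies run *i* with fold *i* of a single partition.

2. **Nested reduced-feature models** (`train_reduced_models()`,
   `weighted_scores()`). Forests are trained for every prefix of the
   ranking — feature sets {1}, {1,2}, ..., {1..n} — and evaluated on pooled
   out-of-fold scores of the training partition (the model's score for a
   subject is the fraction of trees voting ASD). For each model the
   Youden-optimal threshold (`youden_threshold()`) maximizes
   J = sensitivity + specificity − 1 over every distinct ROC operating
   point; that threshold is *frozen* and reused verbatim on the validation
   set later. The "optimal model" maximizes a parsimony-weighted score:
   AUC and feature count are each min–max scaled to the unit interval over
   the family (complexity scaled so that *fewer* features score *higher*),
   then combined as 0.35·AUC + 0.65·complexity — a 2:1 emphasis on
   simplicity. When all AUCs are equal the scaled AUC is defined as 1 for
   every model, and argmax ties resolve toward fewer features.

3. **Blind validation** (`evaluate_on_validation()`). Each family member
   is retrained on the full training partition with its feature set and
   scored on the untouched validation subjects at its frozen threshold;
   AUC, balanced accuracy (the mean of sensitivity and specificity —
   plain accuracy is available via `balanced = FALSE`), sensitivity and
   specificity are reported.

4. **Minimal model** (`mcnemar_test()`, `find_minimal_model()`). Every
   reduced model's per-subject correctness on the validation set is
   compared to the full-feature model's with McNemar's paired test on the
   discordant counts, χ² = (b−c)²/(b+c) with 1 df and **no continuity
   correction** — the uncorrected form is what the printed anchor pairs
   of the reference analyses reproduce. Scanning k upward, the minimal
   model is the smallest feature set whose errors do not differ from the
   full model at α = 0.05. When b + c = 0 the test is defined as χ² = 0,
   p = 1.

`run_pipeline()` chains all of this and returns the ranking, the family
table (training "test" columns and validation "blind" columns side by
side), the weighted scores, and the optimal/minimal selection with its
McNemar table; `tidy()`, `glance()`, `autoplot()` and
`write_report_bundle()` expose the result.

## The synthetic cohort generator

Clinical item-level data of this kind is restricted, so the package ships
a generator (`cohort_spec()`, `generate_cohort()`) that emulates the
*structure* of such cohorts with known ground truth. Each subject's class
is Bernoulli(prevalence); each item has a standard-normal latent severity,
shifted by δ (a standardized mean difference) in the ASD class for planted
informative items; codes 0--3 arise by thresholding at fixed cutpoints
(default `qnorm(c(.5, .75, .9))`, i.e. code mass ≈ 50/25/15/10% in the
non-ASD class — a convention, since no item-level distributions are
published for the real cohorts). Special codes 7/8 then replace observed
codes at a class-independent rate — mirroring their semantics of "peculiar
or abnormal behaviour" without inventing class structure — and entries are
masked missing completely at random (a class-dependent missingness rate
is available for stress tests). The latent-Gaussian design was chosen over
per-code multinomial sampling because it gives the closed form
latent AUC = Φ(δ/√2) per item, an analytic oracle the tests exploit.

Preset layouts (`module_preset()`) reproduce the four published family
sizes — 28 (ADOS module 3), 31 (module 4), 65 and 68 items (either module
plus the 37 ADI-R algorithm items) — at prevalence 0.46 with 5% special
codes and 10% missingness, and plant seven informative ADOS items with δ
falling from 2.0 to 0.8 (combined presets add four ADI-R items at 1.2 to
0.6, emulating the observation-heavy mix reported for such cohorts). These
defaults are fixed study conditions, not tuning knobs.

What passing tests on these cohorts shows: the pipeline recovers a known
importance ordering, concentrates planted items in small models, and
reports chance-level performance when no signal exists. What it does not
show: performance on real clinical data, where items are correlated,
ordinal distributions are skewed in ways the probit model does not match,
and missingness is informative (notably, ADI-R data are absent for a large
fraction of real referrals). Published headline accuracies from clinical
cohorts are therefore not reproduction targets here.

## Numerical choices and edge cases

* **Thresholds.** Candidate cut-points are midpoints between adjacent
  sorted unique scores plus ±∞, with the rule "positive iff
  score ≥ threshold"; this enumerates every achievable confusion table.
  Ties in J break toward higher specificity, then the higher threshold.
  Uninformative (all-equal) scores give J = 0.
* **Weighted score degeneracies.** A singleton family scores 1 by
  definition (scaled AUC and complexity both 1); an all-equal-AUC family
  maps scaled AUC to 1 uniformly.
* **Determinism.** One master seed; per-run, per-fold and per-item
  substreams are derived by stable integer hashing, with the per-item
  permutation stream keyed by the item *id* (not its column position), so
  results are invariant to the physical column order of the input and
  reruns are byte-identical. All derived seeds stay below 2^31.
* **McNemar vs the exact binomial.** The uncorrected χ²(1) tail closely
  tracks the *mid-p* exact binomial sign test (within 0.01 for 25 or more
  discordant pairs); the conventional exact two-sided binomial can differ
  from it by up to ~0.16 near b = c. The package deliberately implements
  the uncorrected χ² form.
* **Summary-statistic t-tests.** `pooled_t_from_summary()` defaults to the
  pooled (Student) form, which is what published degrees of freedom of the
  reference cohort tables imply; a Welch option exists because one
  adult-subsample row reproduces slightly better under unequal variances.
  Cohen's d always uses the pooled SD; the sign convention lists the ASD
  group first (negative t when the ASD mean is higher).

## Problem sizes used in the shipped checks

The package's own checks run the full pipeline on the preset 28-item
cohort (n = 1500) with 100-tree forests — a deliberately scaled-down
forest relative to the procedure's 400-tree default, which leaves ranking
behaviour intact on cohorts of this size while keeping the suite quick to
run — and a 2000-subject signal-free cohort with 5 ranking runs. Structural
checks of the 65- and 68-item families use 200-subject cohorts and small
forests, since only the family's shape is at stake there.

## Known limitations

* Only prefix feature sets of the ranking are considered; there is no
  combinatorial subset search, and no AIC/BIC-style likelihood penalty —
  the weighted score is a design choice, not an information criterion.
* No multiple-testing correction is applied across the per-k McNemar
  tests, matching the procedure being implemented.
* The generator does not emulate item correlations, age/IQ covariates, or
  instrument-specific responder effects.
* How combined ADOS+ADI-R cohorts handle subjects lacking the interview
  entirely is supported only through the missing-as-valid encoding (the
  default) or by subsetting upstream; no imputation is offered.
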