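---
title: "Methods: evaluating a digital clock-and-recall screen against the MMSE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evaluating a digital clock-and-recall screen against the MMSE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Primary-care screening for mild cognitive impairment (MCI) and mild dementia
needs instruments that are brief, sensitive at early disease stages, and as
free as possible of demographic bias. `dcreval` implements a complete
evaluation pipeline for comparing one such instrument — a composite digital
screen made of a digitally analyzed clock drawing (summary score 0–100) and a
three-word delayed recall, combined into a 0–5 score with Green/Yellow/Red
bands (here called the DCR) — against the Mini-Mental State Examination
(MMSE, 0–30).

Because studies of this kind are typically run on access-governed clinical
data, the package ships a synthetic-cohort generator that reproduces the
*statistical structure* the analysis assumes, so that every stage — cohort
construction, scoring, classifier evaluation, misclassification/rescue
tabulation, and bias comparison — is exercisable and testable end to end
without any data download.

# Reference-standard cohorts without circularity

Using expert diagnoses that themselves consulted the MMSE would bias a
DCR-vs-MMSE comparison. The pipeline therefore rebuilds cohorts from three
tests independent of both screens:

* **Memory**: RAVLT long-delay recall, z-scored against age-binned norms;
  impairment when `z <= -1` (configurable to `-1.5` for sensitivity
  analyses). Negative z is worse.
* **Executive**: TMT-B completion time, z-scored the same way; impairment
  when `z >= +1` (positive is worse, i.e. slower).
* **Function**: FAQ total; functional impairment when `FAQ >= 6`; records
  with `FAQ > 9` are excluded as likely beyond the mild stage.

All boundary comparisons are inclusive except the strict exclusion cut,
taking the threshold definitions literally. The decision tree assigns:
healthy (no flags), aMCI (memory only), mdMCI (memory + executive), naMCI
(executive only), and probable mild ADRD (functional impairment together
with any cognitive flag). Cohorts other than healthy collapse into a single
"cognitively impaired" class for the screening analyses; excluded records
are dropped.

**Open branch.** The published tree does not state a label for functional
impairment with *no* cognitive flag. The package excludes such records by
default: a mild-dementia label without any cognitive deficit is not
defensible, and exclusion is auditable. A switch
(`functional_without_cognitive = "probable_mild_ADRD"`) implements the
alternative reading. Severe-functional exclusion is evaluated before the
tree, since it defines the analyzable sample.

Each record is z-scored against its own age bin only (half-open intervals
`[low, high)`, no interpolation), which keeps the oracle arithmetic exact
and matches how tabulated norms are used in practice. The packaged norm
table is synthetic — published norm tables are not redistributable — and
exists to exercise the z-scoring logic, not to be clinically valid.

# The composite screen

The clock summary contributes 0 points below 60, 1 point in `[60, 75)`, and
2 points at 75 or above; the interval rule applies to real-valued summaries
(74.5 scores 1). Each delayed-recall word contributes one point (0–3);
immediate recall is carried through I/O but never scored. Totals 4–5 are
Green, 2–3 Yellow, 0–1 Red; a screen is positive (possible impairment) at
total `<= 3`. The MMSE rule-out label is "unimpaired" at `>= 28`, a
deliberately conservative clinical cutoff. Unanalyzable clocks are
represented as missing summaries, propagate as `NA` points, and are
excluded explicitly from DCR-side denominators — never imputed.

# The synthetic cohort generator

No generative model is published for data of this kind, so the package
defines one — the simplest that makes multi-test agreement non-trivial:

1. A true-state class per participant drawn from a five-class mixture
   (defaults proportional to the observed rules-based cohort frequencies of
   a large multisite screening sample, roughly 47/25/9/10/9%).
2. Demographics drawn independently: age N(71.5, 6.7) clamped to the norm
   coverage `[55, 90)`, 58.9% female, 85.1% White, 9.3% Hispanic, education
   N(15.4, 2.7) years — the sample structure of that same study population.
3. Per-class normal scores for RAVLT, TMT-B, FAQ, MMSE, clock summary and
   delayed recall, coupled through one latent severity factor per
   participant (`severity_correlation`, default 0.5) signed so that worse
   performance co-occurs across tests. Integer instruments are rounded,
   and all scores are clamped to their ranges.
4. 22 clock subscores generated as noisy monotone transforms of the
   summary score — stand-ins for the age-scaled process subscores a real
   drawing-analysis engine would emit.
5. Optional planted demographic shifts (`bias_effects`), expressed in units
   of the test's *marginal population SD* implied by the configuration
   (`config_marginal_sd()`); this is the scale on which subgroup effect
   sizes are conventionally quoted and the scale of the z-scored bias
   analysis.

Default per-class score means/SDs were chosen once so that, against the
packaged norms, each class lands predominantly in its nominal cohort while
leaving realistic overlap (a few percent of healthy records cross an
impairment cut, dementia-class FAQ straddles the exclusion cut). Rounding
and clamping bias configured means slightly near range bounds (e.g. a
healthy FAQ mean of 1 against the floor of 0); fidelity tests therefore use
parameters well inside the bounds, and users planting effects near a bound
should expect attenuation.

**What the generator does not emulate:** pen-stroke/drawing-level data,
audio or speech-recognition errors, administration-time telemetry, visit
schedules, missing-data mechanisms, and any real correlation structure
beyond the single severity factor. Passing pipeline tests on this model
shows the *procedures* are correct and recover planted effects; it says
nothing about how the real instruments perform on real patients.

# Repeated-split screening evaluation

Each of `n_iterations` (default 200) iterations draws a stratified 70/30
train/test partition (class proportions matched within one record). The
training side only is upsampled with replacement until all classes match
the majority count. A probability random forest (ranger, single-threaded,
seeded) is fitted per feature set; all feature sets see the identical
partition within an iteration, so AUC differences are paired. Test-set
metrics are the Mann–Whitney AUC (ties half-credited) and
sensitivity/specificity/PPV/NPV/balanced accuracy at the Youden-optimal
threshold. Per-iteration seeds are drawn once from the master seed, making
the whole experiment a pure function of one integer.

Numerical choices:

* **Forest tuning.** The published tuning rule ("least number of features
  … for as long as the out-of-bag error estimates were over 0.001 and the
  number of trees was within 500") cannot be implemented literally —
  preferring error *above* a floor is self-defeating. The package tunes
  features-per-split over the grid {1, ⌊√p⌋} and keeps the smallest value
  whose out-of-bag error is within 0.001 (`oob_error_floor`) of the best,
  with trees capped at 500: sparser splits are preferred unless they
  measurably cost accuracy. The learner is pluggable (`classifier` in
  `eval_config()`), so the surrounding pipeline is tested with a
  deterministic stub as well.
* **Youden ties.** When several cutpoints attain the maximal
  J = sensitivity + specificity − 1, the lowest threshold is chosen — the
  most sensitive rule, appropriate for screening. Candidate thresholds are
  the observed score values; the rule is "positive if score ≥ t".
* **Permutation test.** The paired test on median AUC differences flips
  the sign of each paired difference independently (equivalent to swapping
  the two models' AUCs within an iteration) and uses the add-one p-value
  `(1 + #{|perm| ≥ |obs|}) / (B + 1)`, so p is never zero and never below
  `1/(B+1)`. Note that for a *median* statistic the null distribution of a
  constant-shift alternative is not degenerate at the extreme — the
  flipped median magnitude equals the shift whenever most signs agree — so
  small p-values come from consistent, not merely large, differences.

# Missed and rescued cases

Among participants with RAVLT-confirmed memory impairment, the rescue table
counts those the MMSE labels unimpaired (`mmse >= 28`), how many of those
the DCR flags (`total <= 3`), and the reverse. Rates carry explicit
denominators; a zero denominator yields an undefined (`NA`) rate rather
than zero, and display rounding is half-up to one decimal while raw
fractions are retained in the object. Published counts for this analysis
use inconsistent denominators across the two screens (a 10.6% figure
implies ≈208 where the MMSE percentage uses 276); the package does not try
to reproduce ambiguous percentages and always reports its denominators.

# The demographic-bias comparison

Three analyses address demographic influence: two-sample Wilcoxon rank-sum
subgroup comparisons (exact for small tie-free samples, tie-corrected
normal approximation otherwise), Poisson regressions of each integer score
on race, ethnicity, education years, sex, age and binary cohort status
(IRLS to tolerance 1e-8, collinear designs refused with the aliased columns
named), and the comparative bootstrap:

On each of `n_iterations` (default 5000) iterations, 100 participants per
factor subgroup are drawn with replacement, and a linear model per screen
predicts that screen's z-scaled score (scaled once, on the full analyzable
sample) from the six predictors above (main effects only, matching the
stated predictor list). The screen's *bias* is the magnitude of the
factor-of-interest coefficient — magnitudes, because "which screen is less
biased" is a comparison of unsigned adjusted subgroup differences; signed
coefficients are retained for audit. The per-iteration difference
(DCR − MMSE) yields a median and a percentile CI (the simplest auditable
choice; BCa was considered and rejected as unwarranted by the procedure's
description). Education enters the model in years but defines subgroups by
a ≥ 15-year split. Singular per-iteration designs are skipped and counted.

**Calibration caveat (computed by this package's own acceptance suite).**
Under a null with no planted effects, the 95% percentile interval covers
zero in ~99–100% of replicate runs, not 95%: drawing a fixed 100 per group
regardless of the source subgroup sizes makes the per-iteration coefficient
noise larger than the sampling noise of the full-sample coefficient, so the
procedure is conservative. This is a property of the resampling scheme
itself, faithfully implemented; interpreting an interval that *excludes*
zero remains sound (the type-I error is below nominal), but the interval
should not be read as an efficient 95% CI.

# Problem sizes used by the tests and acceptance script

Chosen as the package's own scaled-down study conditions:

* Pipeline recovery: n = 800 simulated participants, 50 repeated splits,
  feature sets `dcr` / `mmse` (replaced by pure noise) / `demographics`
  (generated independently of the true state), permutation B = 2000–5000.
* Null calibration of the bias bootstrap: 200 replicate cohorts of
  n = 1000 with 500 bootstrap iterations each.
* Direction recovery: 100 replicate cohorts of n = 4000 with a planted
  0.5-population-SD ethnicity shift on the MMSE only. The size was set by
  a power analysis: with ~9% Hispanic prevalence, the source-sample
  coefficient at n = 1000 is too variable for the direction call to
  replicate in ≥ 90% of runs (observed ≈ 0.82), while n = 4000 stabilizes
  it (≈ 0.98); the per-iteration noise floor is fixed by the 100-per-group
  resample and does not shrink with n.
* Kernel oracles: AUC vs O(n²) pair counting and Youden vs exhaustive
  cutpoint enumeration on 100+ random instances (n ≤ 200); the permutation
  p-value vs full 2^10 sign-flip enumeration at length 10.

# Known limitations

* The generator's single-factor correlation structure is a deliberate
  simplification; real test batteries have richer shared structure.
* Clock subscores are exchangeable noisy copies of the summary; a real
  drawing-analysis engine emits heterogeneous, partially independent
  process measures, so feature-level claims (e.g. variable importance) are
  out of scope.
* Norms are synthetic; absolute cohort frequencies produced by the
  classifier on simulated data are only as meaningful as the configured
  class distributions.
* The bias bootstrap inherits the conservatism described above; comparing
  two screens' bias magnitudes also ignores uncertainty asymmetry when one
  screen's true coefficient is near zero (its magnitude estimate is biased
  upward), which slightly shrinks measured differences.
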