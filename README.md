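# dcreval

Evaluation toolkit for comparing a brief composite digital cognitive screen
— a digitally analyzed clock drawing (summary 0–100) plus a three-word
delayed recall, combined into a 0–5 score with Green/Yellow/Red bands (the
*DCR*) — against the Mini-Mental State Examination (MMSE) for detecting
mild cognitive impairment (MCI) and mild dementia.

It is written for biostatisticians and methods researchers who need to run,
audit, or extend this style of screening-instrument comparison. Because
real cohort data of this kind is typically access-governed, the package
includes a configurable synthetic-cohort simulator so the entire pipeline
is runnable and testable from a single seed.

## What it implements

* **Rules-based cohorts.** To avoid circularity with the screens under
  comparison, cohorts are rebuilt from independent tests: RAVLT long-delay
  recall z-scored against age-binned norms (memory impaired at
  z ≤ −1), TMT-B completion time (executive impaired at z ≥ +1), FAQ
  (functionally impaired at ≥ 6; excluded above 9). A decision tree yields
  healthy / aMCI / mdMCI / naMCI / probable mild ADRD / excluded, and the
  impaired cohorts collapse to a binary label.
* **Composite scoring.** Clock points (0–2 at summary cuts 60 and 75) plus
  recall points (0–3, one per word) give the 0–5 total; bands Green 4–5,
  Yellow 2–3, Red 0–1; screen-positive at total ≤ 3; MMSE rule-out label
  "unimpaired" at ≥ 28.
* **Repeated-split evaluation.** Stratified 70/30 partitions, training-set
  upsampling to the majority class, probability random forests (tuned
  features-per-split, ≤ 500 trees), Mann–Whitney AUC
  (AUC = P(score_impaired > score_unimpaired), ties ½), Youden-optimal
  thresholds (max J = sens + spec − 1, lowest threshold on ties), and a
  paired sign-flip permutation test on median AUC differences with
  p = (1 + #{|perm| ≥ |obs|})/(B + 1).
* **Missed/rescued cross-tabulation.** Among RAVLT-confirmed memory
  impaired participants: how many each screen misses, and how many of one
  screen's misses the other screen catches.
* **Demographic-bias comparison.** Wilcoxon subgroup tests, Poisson score
  regressions, and a comparative bootstrap: 100 participants per subgroup
  resampled 5000 times; per iteration a linear model per screen predicts
  its z-scaled score from race, ethnicity, education, sex, age and cohort
  status; *bias* = |coefficient of the factor of interest|; the percentile
  CI of the per-iteration difference (DCR − MMSE) decides which screen is
  less biased.

See `vignettes/dcr-evaluation-methods.Rmd` for the model, the numerical
choices, and known limitations.

## Worked example

```r
library(dcreval)

norms <- default_norm_table()
pop <- generate_population(simulation_config(n_participants = 706, seed = 42))
lab <- classify_records(pop, norms)
table(lab$cohort)
#>            healthy               aMCI              mdMCI              naMCI
#>                357                160                 64                 62
#> probable_mild_ADRD           excluded
#>                 61                  2

sc <- score_records(lab)
build_rescue_table(sc, norms)
#> RAVLT-confirmed memory impairment (z <= -1): n = 283
#>   missed by MMSE (>= 28): 93 (32.9%)
#>     of those, rescued by DCR (<= 3): 78 (83.9%)
#>   missed by DCR (> 3): 28 (9.9%)
#>     of those, rescued by MMSE (< 28): 13 (46.4%)

rec <- sc[sc$impairment_status != "excluded", ]
labels <- droplevels(rec$impairment_status)
ev <- evaluate_feature_sets(rec, labels,
  eval_config(n_iterations = 20, seed = 1,
              feature_sets = default_feature_sets(rec)[c("dcr", "mmse", "demographics")]))
ev
#> Repeated stratified-split evaluation: 20 iterations, 3 feature set(s)
#>   dcr            median AUC = 0.917 (SD = 0.015)
#>   mmse           median AUC = 0.825 (SD = 0.030)
#>   demographics   median AUC = 0.524 (SD = 0.023)

paired_permutation_median_diff(ev$auc[, "dcr"], ev$auc[, "mmse"], 5000, seed = 2)
#> Paired sign-flip permutation test: median diff = 0.0891, p = 0.0007998 (5000 permutations)

bootstrap_bias_difference(rec, bias_config("ethnicity", n_iterations = 1000, seed = 3))
#> Bootstrapped bias difference (DCR minus MMSE) for ethnicity:
#>   median = 0.009, 95% CI = [-0.180, 0.197] (1000 iterations, 0 singular fits skipped)
#>   -> no significant difference in bias
```

Reading the numbers: on this simulated cohort the clock-and-recall feature
set separates impaired from unimpaired participants better than the MMSE
total (median AUC 0.92 vs 0.83 over 20 paired splits; permutation
p ≈ 8e-4), demographics alone sit at chance (0.52), the DCR recovers 83.9%
of the memory-impaired participants the MMSE's ≥ 28 rule-out misses, and —
with no planted demographic effects — the bias bootstrap correctly finds no
ethnicity-bias difference between the screens.

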