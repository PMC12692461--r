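# registrysynth

Overlap-aware evidence synthesis for multi-registry survival data.

Rare-tumour evidence — appendiceal neoplasms are the motivating case — lives
in registry studies (SEER, NCDB, NCRAS, PALGA, institutional series) whose
patient populations overlap: two NCDB cohorts spanning 2004–2019 contain many
of the same patients. Pooling them as independent double-counts patients;
excluding them discards scarce evidence. `registrysynth` implements a
quantitative alternative for analysts synthesizing such evidence:

* **Overlap weighting.** Pairwise overlap probabilities
  `O_ij = 0.4 T + 0.2 G + 0.3 D + 0.1 C` (temporal, geographic, database,
  criteria components), four-tier categories, and inverse-overlap study
  weights `w_i = 1 / (1 + Σ_j O_ij)`.
* **Overlap-weighted pooling.** Random-effects meta-analysis of log hazard
  ratios (DerSimonian–Laird `τ²`, Hartung–Knapp `t(k−1)` intervals,
  optional study-level bootstrap), with a three-strategy weighting
  sensitivity analysis.
* **Pseudo-IPD reconstruction.** Interval-wise inversion of digitized
  Kaplan–Meier curves into per-patient `(time, event)` records, with
  fidelity validation against known truth.
* **Synthetic cohorts.** Gaussian-copula covariate generation matched to
  published marginal summaries, with pseudo-likelihood model averaging over
  candidate dependence models.
* **Survival modelling and metrics.** Weibull / log-normal / generalized
  gamma fits with two-stage hierarchical pooling; C-index, Hosmer–Lemeshow,
  NRI/IDI, Brier, calibration slope, decision-curve net benefit; five-tier
  rule-based risk assignment.
* **Derived clinical statistics.** Fold-ratios, odds ratios, absolute risk
  reduction, NNT, and E-values for unmeasured confounding.
* **A ground-truth simulator** of overlapping-registry ecosystems so every
  stage is testable offline.

The summary tables of an 18-study appendiceal-neoplasm evidence base
(67,001 patients, 1973–2024) ship as plain-text fixtures, so the whole
pipeline runs without network access.

## Worked example

```r
library(registrysynth)

studies <- load_fixture("table1")          # 18 study records
effects <- load_fixture("table3")          # 7 per-study hazard ratios

# two studies print no histology mix, so their criteria sets fall back to
# the full subtype set (with a warning)
assessment <- suppressWarnings(assess_ecosystem(studies))
assessment
#> <overlap_assessment> 18 studies, 153 pairs
#>   computed study categories: high=15, medium=3, low=0, none=0
#>   weight range: [0.074, 0.180]

pool(effects, overlap_weights = assessment$weights, mode = "inverse_overlap")
#> <pooled_effect> HR 0.711 (95% CI 0.539-0.938), tau^2 0.0692, k=7, mode=inverse_overlap

sens <- sensitivity_max_rel_diff(effects, assessment$weights,
                                 assessment$printed_labels)
sens$max_rel_diff_pct
#> [1] 1.56264

e_value(0.13)   # HIPEC vs systemic chemotherapy, stage IV
#> [1] 14.9
nnt(load_fixture("table4_rates")[["r0_resection_30day_mortality"]])
#> [1] 38
```

Reading: pooling the seven study-level hazard ratios under inverse-overlap
weighting gives a pooled mortality HR of 0.711 (favouring the indexed
treatment/histology contrasts), within 2% of the published 0.723; switching
among the three weighting strategies moves the pooled HR by at most 1.6%,
well inside the published 7.8% robustness bound; and an unmeasured
confounder would need a risk ratio of 14.9 with both treatment and outcome
to explain away the HIPEC effect.

`repro_paper_examples()` prints the full computed-versus-printed table, and
`run_pipeline(pipeline_config(out_dir = "out"))` writes the overlap report,
weights and a JSON summary.

## Package layout

| Area | Files |
|---|---|
| Study records, fixtures, effect estimates | `R/study_model.R` |
| Overlap probabilities and weights | `R/overlap.R` |
| KM curve inversion to pseudo-IPD | `R/km_reconstruct.R` |
| Copula covariate synthesis | `R/covariate_synth.R` |
| Random-effects pooling, sensitivity | `R/pooling.R` |
| Fold ratios, NNT, E-values | `R/effect_stats.R` |
| Parametric fits, metric suite, risk tiers | `R/survival_metrics.R` |
| Ecosystem simulator | `R/synthetic_data.R` |
| Pipeline orchestration | `R/pipeline.R` |

The methods vignette (`vignettes/overlap-aware-synthesis.Rmd`) documents the
model, its assumptions, parameter choices, and known limitations.
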