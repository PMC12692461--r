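---
title: "Overlap-aware evidence synthesis for multi-registry survival data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Overlap-aware evidence synthesis for multi-registry survival data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(registrysynth)
```

## The problem

Evidence on rare tumours such as appendiceal neoplasms is scattered across
registry studies — SEER, NCDB, NCRAS, PALGA and institutional series — whose
patient populations overlap: two NCDB cohorts covering 2004–2019 almost
certainly contain many of the same patients. Pooling such studies as if they
were independent double-counts patients and understates uncertainty, while
excluding "overlapping" studies outright discards scarce evidence.
`registrysynth` implements a quantitative middle road: estimate how much each
study pair overlaps, downweight studies in proportion to their total overlap,
and propagate those weights through a random-effects synthesis. Around this
core it provides the supporting machinery such a synthesis needs —
reconstruction of pseudo individual-patient data (IPD) from published
Kaplan–Meier curves, copula-based synthetic covariates matched to published
summary tables, parametric survival modelling, and a model-evaluation metric
suite — plus a ground-truth simulator so every stage can be validated without
access to restricted registry data.

## Overlap probability and inverse-overlap weights

For each study pair $(i, j)$ the overlap probability is a weighted sum of
four components,

$$O_{ij} = 0.4\,T_{ij} + 0.2\,G_{ij} + 0.3\,D_{ij} + 0.1\,C_{ij},$$

where $T_{ij}$ is the temporal overlap coefficient (calendar years in common
divided by the minimum inclusive study duration), $G_{ij}$ the geographic
overlap (1 same country, 0.5 same continent, 0 otherwise), $D_{ij}$ the
database overlap (1 when the registry sets intersect) and $C_{ij}$ the
Jaccard similarity of inclusion criteria. Pairs are categorised as high
($O \ge 0.70$), medium ($0.30 \le O < 0.70$), low ($0.10 \le O < 0.30$) or
no overlap ($O < 0.10$); lower bounds are closed. Each study is weighted by

$$w_i = \frac{1}{1 + \sum_{j \ne i} O_{ij}},$$

so an isolated study keeps weight exactly 1 and a heavily duplicated study is
shrunk towards (but never to) zero.

Design choices worth knowing:

* **Criteria tokens.** Published studies rarely print machine-readable
  inclusion criteria. By default the histology-subtype set implied by each
  study's histology mix stands in (a GCA-only cohort is `{GCA}`, a mixed
  cohort the full subtype set); studies reporting no histology mix are
  treated as mixed all-subtype cohorts, with a warning. A `criteria_map`
  argument overrides this.
* **Study-level category = maximum pairwise category.** Conservative by
  intent: a study sharing many patients with *any* other study is itself
  high-risk.
* **Component weights are configurable** (`weights =` in
  `overlap_probability()`/`assess_ecosystem()`) for sensitivity analyses;
  the defaults above are the primary analysis.
* **Computed versus transcribed categories.** Applied to the packaged
  18-study table, the max-pairwise rule classifies 15 studies high — the
  printed per-study labels list 7. The formula's inputs (printed periods,
  registries, countries) simply do not reproduce the printed labels, so the
  package reports both side by side and never forces agreement. Downstream,
  the exclusion-sensitivity strategy uses the transcribed labels by default
  (excluding by computed category would drop nearly every registry study);
  `pipeline_config(exclusion_labels = "computed")` switches this.

## Overlap-weighted random-effects pooling

Study effects arrive as hazard ratios with 95% CIs; standard errors are
recovered as $\mathrm{se} = (\log \mathrm{CI}_u - \log \mathrm{CI}_l)/(2
\times 1.96)$, which the packaged per-study CIs support to within 1% (they
are log-symmetric up to printing precision). Pooling is on the log scale:
between-study variance $\tau^2$ by DerSimonian–Laird (the estimator is
documented and deliberately simple; the random-effects model itself is the
commitment, not the specific $\tau^2$ estimator), random-effects weights
$1/(\mathrm{se}_i^2 + \tau^2)$, and a Hartung–Knapp 95% interval — the
weighted residual variance with a $t_{k-1}$ quantile, which behaves far
better than the normal-theory interval at the $k \le 10$ typical of rare
diseases. Overlap weights enter multiplicatively on the random-effects
weights and are renormalised; the pooled estimate therefore always stays
inside the convex hull of the study log-HRs, under every weight mode. A
study-level bootstrap percentile interval (1000 iterations by default) is
available as an alternative.

The three-strategy sensitivity analysis pools under (a) inverse-overlap
weights (primary), (b) unit weights and (c) exclusion of high-overlap
studies, and reports the maximum pairwise relative difference against the
primary estimate. On the packaged tables this is about 1.6%, comfortably
inside the published 7.8% robustness bound.

```{r pooling-example}
assessment <- suppressWarnings(assess_ecosystem(load_fixture("table1")))
effects <- load_fixture("table3")
pool(effects, overlap_weights = assessment$weights, mode = "inverse_overlap")
```

## Kaplan–Meier inversion to pseudo-IPD

A digitized KM curve carries, at each grid time, the fraction of the cohort
still event-free. `reconstruct_ipd()` inverts it interval by interval:
walking the grid with a running risk set of size $n_k$ and running KM value
$\hat S$, the integer event count $d_k$ minimising
$(\hat S (1 - d_k/n_k) - S_k)^2$ is allocated at the interval endpoint. The
search is local (the rounded target $\pm 1$), so each step re-targets the
input curve and rounding errors do not accumulate: for curves that are exact
KM outputs of fully-observed cohorts the recovery is exact, and in general
the reconstructed curve tracks the input within half a risk-set step.

Censoring is the non-identifiable part: a `(time, survival)` sequence alone
cannot distinguish losses during follow-up from administrative cut-off.
The rules, in order of preference: an at-risk table, when supplied, fixes the
number censored in each interval (infeasible tables are rejected, naming the
interval); an optional constant monthly `dropout_rate` may be supplied;
otherwise all unexplained patients are censored administratively at the last
grid time. Event times sit on the grid (the curve is the only information
carrier — no invented within-interval jitter); censoring times are spread
uniformly inside their interval, the only use of the seed.

Reconstruction fidelity is validated end-to-end on simulated studies
(`km_reconstruction_experiment()`): Weibull cohorts spanning shape 1.2–1.8,
median survival 30–90 months and sizes 500–3000 with 20% uniform censoring —
the ranges of the registry curves that motivated the package — are sampled
monthly (emulating digitization), reconstructed, and scored against the true
medians and monthly survival probabilities. Typical results are a
median-survival mean absolute relative error around 1% and a pooled survival
correlation indistinguishable from 1, inside the published bounds (2.3%,
0.94) with a wide margin. Note what this does and does not show: simulated
curves are sampled exactly, so digitization *noise* (hand-traced
coordinates, pixel quantisation) is exercised only through the 0.005
clipping tolerance of `survival_curve()`, not through the fidelity
experiment.

## Copula-based covariate synthesis

`generate_cohort()` draws a latent multivariate normal vector with unit
variances and a specified correlation matrix and pushes each coordinate
through the variable's quantile function: categorical variables by
probability-slice inversion of the latent CDF (for ordered categories the
slice boundaries are ordinal thresholds on the latent scale), continuous
variables (age) by a truncated-normal quantile map matched to the printed
median (median ≈ mean is assumed; the sd is configurable because summary
tables rarely print one). Several candidate dependence models can be
averaged: `weight_candidates()` scores each candidate by the multinomial
pseudo-likelihood of reference pairwise contingency tables under the
candidate's implied cell probabilities (1-D quadrature of bivariate-normal
rectangles), converts to BIC, and weights by $\exp(-\mathrm{BIC}/2)$; the
generator then draws each patient's block from a candidate selected with
those probabilities. This is a deliberately small realisation of model
averaging over copulas — the candidate set is independence plus Gaussian
copulas, and no vine structure learning is attempted.

At $n = 10{,}000$ the generated marginals sit within a few tenths of a
percentage point of their targets, against published agreement bounds of 5%
(covariate distributions) and ±3% (summary-table characteristics).

## Parametric survival models and the metric suite

Per-study fits (`fit_parametric()`) use maximum likelihood with right
censoring via `flexsurv`: Weibull, log-normal, generalized gamma (which
nests the other two) and exponential. The hierarchy across studies is
two-stage: each unconstrained-scale parameter is pooled with the same
overlap-aware random-effects machinery used for hazard ratios, giving
pooled parameters plus a between-study variance per parameter. This is a
deliberate, desk-scale substitute for a joint hierarchical likelihood: the
estimand (population parameters with between-study heterogeneity) is the
same, the machinery is testable, and a full MCMC treatment is out of scope.

The evaluation suite implements Harrell's C-index (0.5 credit for tied
scores; at tied times a pair is usable only when exactly one member has an
event), the Hosmer–Lemeshow decile test with empty-bin merging, NRI/IDI,
the Brier score, a logistic calibration slope, and decision-curve net
benefit $TP/n - FP/n \cdot p_t/(1 - p_t)$. Each has closed-form reference
points exercised in the tests (perfect predictors, classify-none, identical
reclassification), and the C-index is checked against both a brute-force
pair count and `survival::concordance`.

Risk-tier assignment maps cohort-level descriptors to patient-level rules,
evaluated in fixed precedence with first match winning and intermediate as
default: very-high (three or more adverse factors among signet-ring
histology, stage IV, positive margins, HIPEC-level complexity), high (any
one of the first three), intermediate (MAC/NMAC), low (GCA, early stage,
margins not positive), very-low (NET/carcinoid, localized, age < 55).
Records missing histology or stage are flagged "insufficient data", never
guessed.

## The ground-truth simulator

`simulate_ecosystem()` is first-class, tested code, not a fixture: per-study
cohorts with a histology mix, histology-specific Weibull survival, a
proportional-hazards treatment contrast ($\mathrm{HR} = 0.7$ by default),
and uniform censoring calibrated to a target fraction (20% by default).
Patients shared between overlapping registries are *exact duplicates* —
the worst case for double counting, which is precisely what inverse-overlap
weighting guards against — and the pairwise shared fractions are the
ecosystem's implied overlap matrix. Per-study hazard ratios are estimated
with a Weibull AFT fit transformed to the PH scale, keeping the package free
of semiparametric machinery.

`default_paper_like_spec()` freezes the simulation conditions to the
published cohort's magnitudes: ten studies with sample sizes between 315
and 6800 (values taken from the summary table), periods within 1973–2020,
SEER-like and NCDB-like blocks sharing 15% of patients pairwise (the largest
fraction the chosen sample sizes can host once every pair's duplicates are
materialised), one independent non-US institutional series, the published
median histology mix renormalised, and Weibull parameters implying the
published survival ordering (NET ≈ 89% five-year OS down to SRCC ≈ 27%,
MAC median ≈ 80 months).

Problem sizes used by the validation experiments: the reconstruction
experiment runs 10 studies up to $n = 3000$; the end-to-end coverage check
pools 7 studies of 250 patients over 500 replicates (500 rather than 200
because the Monte-Carlo error of a coverage proportion at 200 replicates is
about ±2%, too coarse to resolve a 90% bound against a ~93% truth); copula
checks run at $n = 10{,}000$.

## Numerical conventions and degenerate inputs

* Years are inclusive; duration = end − start + 1. Proportions are stored as
  fractions; percent strings are parsed.
* A point CI (`lo == hi`) yields `se = 0` and is flagged degenerate;
  degenerate effects are rejected by the pooling functions rather than
  silently given infinite weight.
* `dl_tau2()` clamps at zero; single-study "pools" return the study itself.
* Curve validation clips digitization inversions up to 0.005 probability to
  the running minimum and rejects anything larger; medians are reported as
  the first grid time with $S \le 0.5$ and are absent (NA) when never
  reached.
* NNT is rounded to the nearest integer (which reproduces all three printed
  values: 38, 100, 2); fold-ratios are reported to one decimal. For the
  printed margin rates the 3.4-fold figure corresponds to the risk ratio
  (3.36), not the odds ratio (3.45); `effect_stats()` computes and labels
  both.
* E-values invert protective ratios first and satisfy
  $E(\mathrm{hr}) = E(1/\mathrm{hr})$ exactly.
* All stochastic stages take explicit seeds and restore the caller's RNG
  state.

## Known limitations

* Overlap probabilities are heuristic: the component weights are fixed by
  convention, criteria similarity leans on histology sets when criteria are
  unprinted, and the formula demonstrably does not reproduce the transcribed
  per-study labels of the packaged table (both are reported).
* Inverse-overlap weighting reduces the influence of duplicated studies but
  does not model the induced correlation between study estimates; the
  end-to-end simulation shows interval coverage holding near nominal at the
  default sharing levels, not under arbitrary ones.
* KM inversion inherits the information limits of published curves: censoring
  within follow-up is unidentifiable without at-risk tables, and event times
  are discretised to the digitization grid.
* The copula generator matches marginals and pairwise latent correlations;
  it does not learn higher-order dependence and cannot manufacture
  information absent from the published summaries. Passing its agreement
  checks says the generator hits its targets — not that synthetic patients
  are exchangeable with real registry records.
* The mixed-histology subgroup pooled value printed in the source tables
  (0.748 from four studies) is not reproducible from the printed CIs by
  standard fixed- or random-effects combinations; the package does not force
  it.
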