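---
title: "Measuring health inequality with equigap: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring health inequality with equigap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(equigap)
```

## The monitoring problem

A binary coverage indicator — the packaged example is ANC4+, whether a woman
with a recent live birth received antenatal care at least four times — is
disaggregated by *equity stratifiers* (dimensions): wealth quintile,
maternal education, urban/rural residence and subnational region. Wealth and
education are **ordered** dimensions: one end is advantaged a priori.
Residence is **binary** with urban advantaged. Region is **non-ordered**:
the reference must be chosen empirically as the best-performing region. For
a favourable indicator (higher is better) the reference group is always the
best-off subgroup.

Each dimension is summarised by four measures. With `y_ref` and `y_comp` the
reference and comparison subgroup coverages (percent) and `mu` the national
average:

* Difference `D = y_ref - y_comp` (pp) and Ratio `R = y_ref / y_comp`
  contrast the two extreme subgroups only;
* `PAR = y_ref - mu` (pp) and `PAF = 100 * PAR / mu` (%) are
  population-weighted through `mu`, so they account for subgroup sizes.

Using absolute and relative, simple and complex measures together is
deliberate: a single measure can mislead when subgroup shares shift, and the
four can disagree in magnitude while agreeing in direction.

## Survey estimation

Subgroup coverage is the weighted domain mean
`p_g = sum_{i in g} w_i y_i / sum_{i in g} w_i`, reported on the 0–100 scale.
Its variance is Taylor-linearized for a stratified multi-stage design under
the with-replacement-PSU approximation that is standard for DHS-type
surveys: with linearized scores
`z_i = w_i (y_i - p_g) 1{i in g} / sum_{g} w_i`, cluster totals `z_hc` are
formed per PSU and the variance is
`sum_h n_h/(n_h - 1) sum_c (z_hc - zbar_h)^2`. Only the first-stage units
(clusters within strata) enter, which is conservative for without-replacement
designs. A stratum with a single PSU contributes zero variance, with a
warning. The variance machinery is implemented directly in the package (it
is a few lines for a domain ratio estimator) and is validated three ways: a
brute-force per-record oracle for the point estimates, an
ignoring-clustering comparison that must understate the SE under
intra-cluster correlation, and replicate-based interval coverage on
synthetic surveys with known truth.

Confidence intervals for prevalences are built on the log-odds scale
(logit-Wald) and mapped back, giving the asymmetric, range-respecting
intervals seen in published tables; at an estimate of exactly 0 or 100 the
logit degenerates and an exact Clopper–Pearson interval is substituted
(flagged) when an effective sample size is available. z is fixed at 1.96 for
the 95% level — matching the convention of the published tables — and at the
normal quantile otherwise.

Subgroups with fewer than 25 unweighted observations are flagged
`suppressed` (a DHS reporting convention; configurable) but never silently
dropped. Reported populations can be unweighted counts (default) or weighted
totals; published tables do not always say which they print, so both are
supported.

## Measure uncertainty

* **D**: the two extreme subgroups share no records, and in the stratified
  designs considered here largely no PSUs, so they are treated as
  independent: `se_D^2 = se_ref^2 + se_comp^2`.
* **R**: delta method on the log scale,
  `se_logR^2 = (se_ref/y_ref)^2 + (se_comp/y_comp)^2`, exponentiated — this
  keeps the interval positive and asymmetric.
* **PAR**: delta method on `y_ref - mu`. The reference subgroup is *part of*
  the national average, so the two are positively correlated; the package
  approximates `Cov(y_ref, mu) = s_ref * Var(y_ref)` with `s_ref` the
  reference group's population share, giving
  `Var(PAR) = Var(ref) + Var(mu) - 2 s_ref Var(ref)`. Ignoring the
  covariance (`cov_method = "independent"`) over-widens the interval; the
  exact formula used by established toolkits is not published, so the
  method is configurable and this default is the package's own choice.
* **PAF**: `PAR` and its interval bounds scaled by `100/mu`. The PAR/PAF
  coupling (`PAF = 100*PAR/mu`, bounds included) therefore holds exactly by
  construction, an invariant the published bound pairs also satisfy at
  their printed precision.

Significance is the interval-excludes-null rule: 0 for D/PAR/PAF, 1 for R.
No multiplicity adjustment is made across the 16 dimension × measure cells,
matching standard monitoring practice.

Two conventions deserve note. Negative PAR estimates can only arise from
estimation noise (the reference is the best-off subgroup), and are truncated
to 0 and flagged, with the interval widened to include 0 so the invariant
`lower <= estimate <= upper` survives truncation. Ties in the empirical
reference selection for non-ordered dimensions are broken by category-list
order and flagged.

## Working from published tables

Published disaggregation tables carry an estimate, a 95% interval and a
population per subgroup, but no standard errors. `summaries_from_published()`
back-derives a symmetric-scale `se = (upper - lower) / (2 * 1.96)`; the
original asymmetric bounds are kept verbatim. When the national row prints
no interval (as the packaged Angola table does), `Var(mu)` is rebuilt per
dimension as `sum_g s_g^2 Var(y_g)` from that dimension's subgroups. These
approximations are adequate for measure-level intervals; they cannot recover
the exact design-based subgroup intervals, which require microdata.

The packaged benchmark (`reproduce_benchmark()`) recomputes all 16 measures
from the published Angola 2015–16 subgroup table and compares them with the
published measure values at a tolerance of 0.02, which absorbs the rounding
of the printed two-decimal inputs.

## The synthetic generator

Since the real microdata are access-restricted, validation uses a generator
that emulates their design: strata are region × urban/rural (36 by default),
with a fixed number of clusters per stratum and women per cluster — a
stratified two-stage cluster sample. Defaults are the package's study
conditions, chosen once:

* 18 regions with population shares proportional to the published analysis
  denominators (Luanda ≈ 32%), urban fractions per region picked to give a
  ~60% urban population;
* 10 clusters × 24 women per stratum → 8,640 women, near the ~8,500
  analysis denominator being emulated;
* a logistic outcome model `logit p = b0 + b_wealth + b_edu + b_urban +
  b_region + u_cluster` with `u_cluster ~ N(0, 0.3^2)` (a modest
  intra-cluster correlation, ICC ≈ 0.03) and effects calibrated so the true
  subgroup coverages mimic the published gradients (poorest ≈ 31%, richest
  ≈ 88%, rural ≈ 38%, urban ≈ 77%, national ≈ 62%);
* wealth and education drawn from residence-specific category probabilities
  (urban skews rich and educated), so stratifiers are correlated as in real
  DHS data;
* weights = inverse stratum selection probability × mean-1 lognormal noise
  (sigma 0.3), normalized to mean 1. Equal per-stratum samples against very
  unequal region populations give the weight dispersion — and the attendant
  design effects — characteristic of DHS designs.

One integer seed governs all draws in a documented order (cluster effects,
wealth, education, outcome, weight noise), so identical configurations are
byte-identical. The truth object carries every cell's marginal outcome
probability (the cluster effect is integrated out numerically) and
population share; true subgroup coverages and the national average are
share-weighted means of the cells, making "estimator recovers truth" a
well-defined test.

What the generator does **not** emulate: non-response and its adjustment,
the two-phase DHS frame, spatial correlation beyond the cluster intercept,
item missingness, and any misreporting of the outcome. Passing tests
therefore demonstrate the estimators' frequentist properties under a
correctly specified complex design, not robustness to those real-data
features.

## Validation problem sizes

The test suite validates, at sizes chosen to balance statistical resolution
against runtime:

* unbiasedness and interval coverage on 500 replicates of the default
  conditions at n = 20,160 (36 strata × 14 clusters × 40 women): subgroup
  biases < 0.3 pp, 95% interval coverage for subgroup coverage and for D
  within 0.95 ± 0.02;
* false-positive rates for D and R at a flat truth (all effects zero,
  coverage 50%) over 500 replicates: ≤ 7%;
* large-sample recovery on a proportionate two-region design at n = 104,000
  over 100 replicates, where a 1 pp recovery band is a ≈3-sigma
  requirement for the smallest (quintile) subgroups. Single-survey recovery
  checks use proportionate designs because under the DHS-like default
  allocation the weight variation alone puts subgroup sampling error near
  1.5 pp at n ≈ 20,000 — a design effect, not an estimator defect, and it is
  the replicate-based checks that assess the estimator under that design.

## Limitations

* The PAR interval rests on an approximate covariance; with microdata an
  exact linearized covariance between the domain and overall estimator
  could be computed, and would be the natural extension.
* Back-derived SEs from printed intervals inherit printed rounding;
  measure-level agreement below ~0.02 should not be over-interpreted.
* Only pairwise-contrast measures are implemented. Regression-based
  measures (slope/relative index of inequality, concentration index),
  multi-survey trends and decomposition of drivers are out of scope.
* The estimators assume the first-stage clusters are sampled
  with replacement within strata; certainty PSUs and collapsed strata are
  not handled beyond the single-PSU warning.
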