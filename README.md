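# equigap

Survey-weighted disaggregation of a binary health-coverage indicator and
WHO-style summary measures of within-country health inequality, with 95%
uncertainty intervals.

## The problem

National coverage averages hide who is being left behind. Health-inequality
monitoring disaggregates an indicator — here, the share of women receiving
antenatal care at least four times during pregnancy (ANC4+) — by *equity
stratifiers*: wealth quintile, maternal education, urban/rural residence and
subnational region. Each dimension is then summarised by four measures, two
simple and two that weight subgroups by population size:

- **Difference** `D = y_ref − y_comp` (percentage points; absolute, simple),
- **Ratio** `R = y_ref / y_comp` (unitless; relative, simple),
- **Population Attributable Risk** `PAR = y_ref − μ` (percentage points;
  absolute, complex): the national gain if every subgroup attained the
  reference level,
- **Population Attributable Fraction** `PAF = 100 · PAR / μ` (relative,
  complex),

where `μ` is the survey-weighted national average and `y_ref`, `y_comp` are
the reference (advantaged: richest, secondary+, urban, best-performing
region) and comparison subgroup coverages. Inequality is absent at `D = 0`,
`R = 1`, `PAR = PAF = 0`; a measure is statistically significant when its
95% uncertainty interval excludes that null value.

The package is aimed at users of DHS/MICS-style complex surveys who want
these measures with design-based uncertainty, either from unit-level
microdata or from an already-published disaggregation table. Subgroup
prevalences use sampling weights with Taylor-linearized variance under a
stratified cluster (with-replacement PSU) design and logit-scale confidence
intervals; measure intervals are delta-method. A DHS-like synthetic survey
generator with known truth supports validation end to end.

## Worked example

The packaged data are the published ANC4+ coverage estimates for Angola
(2015–16 DHS): 28 subgroup rows plus the national average μ = 61.4464%.

```r
library(equigap)

tab <- angola_anc4_2015()
fit <- equigap_published(tab$subgroups, tab$national)
round(coef(fit), 2)
#>   economic_status_D   economic_status_R economic_status_PAR economic_status_PAF
#>               54.15                2.59               26.73               43.51
#>         education_D         education_R       education_PAR       education_PAF
#>               43.42                2.15               19.89               32.38
#>         residence_D         residence_R       residence_PAR       residence_PAF
#>               34.35                1.87               12.31               20.04
#>            region_D            region_R          region_PAR          region_PAF
#>               51.71                2.64               21.78               35.45
```

Reading the first row: ANC4+ coverage among the richest quintile exceeds the
poorest by 54.15 percentage points (D), is 2.59 times higher (R), and
closing the gap to the richest group's level would raise national coverage
by 26.73 points (PAR), i.e. by 43.5% of its current value (PAF).
`confint(fit)` gives the uncertainty intervals and
`summary(fit)` prints the full disaggregation and measures tables.

From microdata the same analysis is one call:

```r
sim <- generate_survey(synthetic_config(seed = 7))
fit <- equigap(anc4 ~ wealth_quintile + education + residence + region,
               sim$records, weights = "weight", strata = "stratum_id",
               cluster = "cluster_id", dimensions = synthetic_dimensions())
```

A thin command-line wrapper (`inst/cli/equigap-cli.R`) exposes `simulate`,
`disaggregate`, `measures` and `benchmark` subcommands.

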