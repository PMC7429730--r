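Package: equigap
Title: Survey-Weighted Disaggregation and Summary Measures of Health Inequality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Disaggregates a binary health-coverage indicator from complex
    survey microdata by equity stratifiers (wealth quintile, education,
    residence, subnational region) and computes the four WHO-style summary
    measures of inequality -- Difference, Ratio, Population Attributable
    Risk and Population Attributable Fraction -- with 95% uncertainty
    intervals and significance calls. Subgroup prevalences use sampling
    weights with Taylor-linearized variance for stratified cluster designs
    and logit-scale confidence intervals. Analyses can start from unit-level
    records or from published subgroup summary tables; a DHS-like synthetic
    survey generator with known truth supports validation, and a packaged
    benchmark reproduces published estimates of antenatal-care (ANC4+)
    coverage inequality in Angola.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, tools
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
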