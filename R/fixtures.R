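## Packaged published tables: ANC4+ coverage in Angola, 2015-16 DHS, as
## disseminated through the WHO Health Equity Monitor. Shipped as plain CSV
## under inst/extdata so the full measure pipeline can run without the
## access-restricted microdata.

equigap_extdata <- function(file) {
  path <- system.file("extdata", file, package = "equigap")
  if (path == "")  # during development, before installation
    path <- file.path("inst", "extdata", file)
  if (!file.exists(path)) stop("packaged fixture not found: ", file)
  path
}

#' Published ANC4+ subgroup coverage, Angola 2015-16
#'
#' The published disaggregation table: coverage of four-or-more antenatal
#' care visits among women with a recent live birth, by wealth quintile (5),
#' maternal education (3), place of residence (2) and subnational region
#' (18), each with a 95\% interval and a population count, plus the national
#' average row (61.4464\%, population 8,492). Values are exactly as printed;
#' standard errors are back-derived from the intervals via
#' [summaries_from_published()].
#'
#' @return list with `subgroups` (a `subgroup_estimates` data frame, 28
#'   rows) and `national` (a `national_average` object; its `se` is `NA`
#'   because the published national row prints no interval).
#' @seealso [angola_anc4_2015_measures()], [reproduce_benchmark()]
#' @export
angola_anc4_2015 <- function() {
  read_subgroup_summaries(equigap_extdata("angola_anc4_2015_subgroups.csv"))
}

#' Published summary measures of ANC4+ inequality, Angola 2015-16
#'
#' The published benchmark values: Difference, Ratio, PAR and PAF with 95\%
#' uncertainty intervals for each of the four dimensions (16 rows), exactly
#' as printed. Used by [reproduce_benchmark()] as the expected side of the
#' comparison.
#'
#' @return data frame with columns `dimension, measure, estimate, ui_lower,
#'   ui_upper`.
#' @export
angola_anc4_2015_measures <- function() {
  read.csv(equigap_extdata("angola_anc4_2015_measures.csv"),
           stringsAsFactors = FALSE)
}
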