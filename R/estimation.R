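## Survey-weighted prevalence estimation with Taylor-linearized variance for
## stratified multi-stage designs (with-replacement PSU approximation).
## All user-facing estimates are on the percentage scale 0-100; probabilities
## are internal only.

# z quantile for a confidence level; fixed at the conventional 1.96 for 95%.
z_for_level <- function(level) {
  if (isTRUE(all.equal(level, 0.95))) 1.96 else qnorm(1 - (1 - level) / 2)
}

# Linearized estimate + SE (0-1 scale) of a weighted domain proportion under
# a stratified cluster design. `domain` is a logical vector; variance sums
# between-PSU squared deviations of linearized cluster totals within strata,
# scaled by n_h/(n_h - 1). Strata with a single PSU contribute zero variance
# (with a warning), as certainty PSUs do under the WR approximation.
svy_domain_mean <- function(y, w, strata, cluster, domain = NULL) {
  if (is.null(domain)) domain <- rep(TRUE, length(y))
  wd <- sum(w[domain])
  if (wd <= 0) return(list(estimate = NA_real_, se = NA_real_, n = 0L))
  est <- sum(w[domain] * y[domain]) / wd
  # linearized score, zero outside the domain
  z <- numeric(length(y))
  z[domain] <- w[domain] * (y[domain] - est) / wd
  psu <- paste(strata, cluster, sep = "\r")
  tot <- rowsum(z, psu, reorder = FALSE)
  psu_stratum <- strata[!duplicated(psu)]
  v <- 0
  single <- FALSE
  for (h in unique(psu_stratum)) {
    th <- tot[psu_stratum == h, 1L]
    nh <- length(th)
    if (nh < 2L) { single <- TRUE; next }
    v <- v + nh / (nh - 1) * sum((th - mean(th))^2)
  }
  if (single)
    warning("stratum with a single PSU contributes no variance", call. = FALSE)
  list(estimate = est, se = sqrt(v), n = sum(domain))
}

# SE ignoring the clustering (weighted iid approximation); used for design
# sanity checks, not for reporting.
svy_iid_se <- function(y, w, domain = NULL) {
  if (is.null(domain)) domain <- rep(TRUE, length(y))
  wd <- sum(w[domain])
  est <- sum(w[domain] * y[domain]) / wd
  sqrt(sum((w[domain] * (y[domain] - est))^2)) / wd
}

#' Confidence interval for a prevalence on the percentage scale
#'
#' Computes a logit-scale Wald interval: the estimate is transformed to the
#' log-odds scale, a symmetric interval is built there using the delta-method
#' standard error, and the bounds are mapped back to percent. This yields the
#' asymmetric, range-respecting intervals conventional for survey prevalence
#' reporting. At the boundaries (0 or 100\%) the logit transform degenerates;
#' if an effective sample size is supplied an exact Clopper-Pearson interval
#' is used instead and the result is flagged, otherwise the degenerate
#' interval (estimate, estimate) is returned flagged.
#'
#' @param estimate prevalence in percent (0-100).
#' @param se standard error of the estimate, percent scale.
#' @param level confidence level (default 0.95; z fixed at 1.96 there).
#' @param n_eff optional effective sample size for the boundary fallback.
#' @return numeric vector `c(lower, upper)` in percent; attribute
#'   `method` is `"logit_wald"`, `"clopper_pearson"` or `"degenerate"`.
#' @examples
#' estimate_interval(50, 5)   # c(40.32, 59.68)
#' @export
estimate_interval <- function(estimate, se, level = 0.95, n_eff = NULL) {
  stopifnot(length(estimate) == 1L, length(se) == 1L, se >= 0,
            estimate >= 0, estimate <= 100)
  z <- z_for_level(level)
  if (se == 0)
    return(structure(c(estimate, estimate), method = "degenerate"))
  p <- estimate / 100
  s <- se / 100
  if (p <= 0 || p >= 1) {
    if (!is.null(n_eff) && is.finite(n_eff) && n_eff > 0) {
      x <- round(p * n_eff)
      a <- 1 - level
      lo <- if (x == 0) 0 else qbeta(a / 2, x, n_eff - x + 1)
      hi <- if (x >= n_eff) 1 else qbeta(1 - a / 2, x + 1, n_eff - x)
      return(structure(100 * c(lo, hi), method = "clopper_pearson"))
    }
    return(structure(c(estimate, estimate), method = "degenerate"))
  }
  l <- qlogis(p)
  sl <- s / (p * (1 - p))
  structure(100 * plogis(l + c(-1, 1) * z * sl), method = "logit_wald")
}

# Assemble a subgroup-estimates data frame row set; shared by the unit-level
# and published-summary paths.
new_subgroup_estimates <- function(dimension, subgroup, estimate, se,
                                   ci_lower, ci_upper, population,
                                   suppressed = FALSE) {
  out <- data.frame(
    dimension = dimension, subgroup = subgroup, estimate = estimate,
    se = se, ci_lower = ci_lower, ci_upper = ci_upper,
    population = population, suppressed = suppressed,
    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("subgroup_estimates", "data.frame")
  out
}

#' Survey-weighted subgroup prevalence for one dimension
#'
#' For each category of `dimension` present in the records, computes the
#' weighted prevalence (percent), its Taylor-linearized standard error under
#' the stratified cluster design, and a logit-scale confidence interval.
#' Subgroups with fewer unweighted observations than `suppress_below` are
#' flagged `suppressed` (DHS reporting convention) but never dropped.
#'
#' @param records data frame of unit-level records with columns `outcome`
#'   (0/1), `weight` (> 0), `stratum_id`, `cluster_id`, and a column named
#'   after the dimension.
#' @param dimension a [dimension_spec()].
#' @param level confidence level, default 0.95.
#' @param population `"unweighted"` (count of records, default) or
#'   `"weighted"` (sum of weights) for the reported population column.
#' @param suppress_below minimum unweighted subgroup size; smaller subgroups
#'   are flagged. Default 25.
#' @return a `subgroup_estimates` data frame: one row per category, columns
#'   `dimension, subgroup, estimate, se, ci_lower, ci_upper, population,
#'   suppressed`.
#' @seealso [national_average()], [equigap()]
#' @export
weighted_prevalence <- function(records, dimension, level = 0.95,
                                population = c("unweighted", "weighted"),
                                suppress_below = 25) {
  population <- match.arg(population)
  stopifnot(inherits(dimension, "dimension_spec"))
  check_records(records, dimension$name)
  vals <- as.character(records[[dimension$name]])
  cats <- dimension$categories[dimension$categories %in% vals]
  extra <- setdiff(unique(vals), dimension$categories)
  if (length(extra))
    stop("records contain categories not in dimension '", dimension$name,
         "': ", paste(extra, collapse = ", "), call. = FALSE)
  rows <- lapply(cats, function(g) {
    dom <- vals == g
    fit <- svy_domain_mean(records$outcome, records$weight,
                           records$stratum_id, records$cluster_id, dom)
    est <- 100 * fit$estimate
    se <- 100 * fit$se
    ci <- estimate_interval(est, se, level, n_eff = fit$n)
    pop <- if (population == "weighted") sum(records$weight[dom]) else fit$n
    data.frame(dimension = dimension$name, subgroup = g, estimate = est,
               se = se, ci_lower = ci[1L], ci_upper = ci[2L],
               population = pop, suppressed = fit$n < suppress_below,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  class(out) <- c("subgroup_estimates", "data.frame")
  out
}

#' Survey-weighted national average
#'
#' Weighted prevalence over all records, with the same linearized variance
#' method as [weighted_prevalence()]. This is the mu against which the
#' population-attributable measures (PAR, PAF) contrast the reference group.
#'
#' @inheritParams weighted_prevalence
#' @return list of class `national_average` with `estimate`, `se`,
#'   `ci_lower`, `ci_upper` (percent) and `population`.
#' @export
national_average <- function(records, level = 0.95,
                             population = c("unweighted", "weighted")) {
  population <- match.arg(population)
  check_records(records)
  fit <- svy_domain_mean(records$outcome, records$weight,
                         records$stratum_id, records$cluster_id)
  est <- 100 * fit$estimate
  se <- 100 * fit$se
  ci <- estimate_interval(est, se, level, n_eff = fit$n)
  pop <- if (population == "weighted") sum(records$weight) else fit$n
  structure(list(estimate = est, se = se, ci_lower = ci[1L],
                 ci_upper = ci[2L], population = pop),
            class = "national_average")
}

#' @export
print.national_average <- function(x, ...) {
  cat(sprintf("National average: %.2f%% (95%% CI %.2f, %.2f), population %s\n",
              x$estimate, x$ci_lower, x$ci_upper,
              format(x$population, big.mark = ",")))
  invisible(x)
}

#' Back-derive standard errors from published subgroup summaries
#'
#' Published disaggregation tables report an estimate, a 95\% interval and a
#' population count, but not the standard error. This recovers a symmetric
#' approximation se = (upper - lower) / (2 * 1.96), which is what the
#' measure-level uncertainty propagation needs; the original (possibly
#' asymmetric) bounds are preserved verbatim in the output.
#'
#' @param rows data frame with columns `dimension`, `subgroup`, `estimate`,
#'   `ci_lower`, `ci_upper`, `population`.
#' @param level confidence level the published intervals used, default 0.95.
#' @return a `subgroup_estimates` data frame with the derived `se` column.
#' @examples
#' summaries_from_published(data.frame(
#'   dimension = "economic_status", subgroup = "Quintile 1 (poorest)",
#'   estimate = 34.03, ci_lower = 30.44, ci_upper = 37.82, population = 1674))
#' @export
summaries_from_published <- function(rows, level = 0.95) {
  need <- c("dimension", "subgroup", "estimate", "ci_lower", "ci_upper",
            "population")
  miss <- setdiff(need, names(rows))
  if (length(miss))
    stop("published summaries missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  bad <- which(!(rows$ci_lower <= rows$estimate &
                 rows$estimate <= rows$ci_upper))
  if (length(bad))
    stop("malformed interval (lower <= estimate <= upper violated) for: ",
         paste(rows$subgroup[bad], collapse = ", "), call. = FALSE)
  z <- z_for_level(level)
  new_subgroup_estimates(
    dimension = as.character(rows$dimension),
    subgroup = as.character(rows$subgroup),
    estimate = rows$estimate,
    se = (rows$ci_upper - rows$ci_lower) / (2 * z),
    ci_lower = rows$ci_lower, ci_upper = rows$ci_upper,
    population = rows$population)
}

# Validate a unit-level record frame; `extra` are dimension columns that must
# also be present. Reports offending row numbers for data errors.
check_records <- function(records, extra = character()) {
  need <- c("outcome", "weight", "stratum_id", "cluster_id", extra)
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(records) == 0L) stop("no records", call. = FALSE)
  bad <- which(!records$outcome %in% c(0, 1))
  if (length(bad))
    stop("non-binary outcome at row(s): ",
         paste(head(bad, 5L), collapse = ", "), call. = FALSE)
  bad <- which(!(records$weight > 0))
  if (length(bad))
    stop("non-positive weight at row(s): ",
         paste(head(bad, 5L), collapse = ", "), call. = FALSE)
  invisible(TRUE)
}
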