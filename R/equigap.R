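#' Fit a health-inequality analysis from unit-level survey records
#'
#' The main modelling interface. Given unit-level records of a binary
#' coverage indicator under a stratified cluster design, disaggregates the
#' indicator by each equity stratifier on the right-hand side of `formula`
#' (survey-weighted prevalence with Taylor-linearized standard errors and
#' logit-scale intervals), estimates the national average mu, and computes
#' the four summary measures of inequality (D, R, PAR, PAF) with 95\%
#' uncertainty intervals and significance calls for every dimension.
#'
#' @param formula e.g. `anc4 ~ wealth_quintile + education + residence +
#'   region`; the left-hand side must be a 0/1 indicator, each right-hand
#'   term a stratifier column in `data`.
#' @param data data frame of unit-level records.
#' @param weights sampling weights: a column name (character) or a numeric
#'   vector. Required for design-based inference; defaults to equal weights.
#' @param strata,cluster design identifiers: column names or vectors.
#'   Defaults: one stratum; each record its own cluster (i.e. iid).
#' @param dimensions named list of [dimension_spec()] objects keyed by
#'   right-hand-side variable; missing specs are inferred (ordered factors
#'   become ordered dimensions with the last level advantaged, everything
#'   else non-ordered).
#' @param level confidence level for all intervals (default 0.95, z = 1.96).
#' @param population report subgroup populations as `"unweighted"` record
#'   counts (default) or `"weighted"` sums of weights.
#' @param suppress_below flag subgroups with fewer unweighted records than
#'   this (default 25).
#' @param cov_method covariance handling in the PAR interval, see
#'   [ineq_par()].
#' @return an object of class `"equigap"`: a list with `disaggregation`
#'   (subgroup estimates, all dimensions), `national` (mu), `measures`
#'   (4 measures x dimensions), `dimensions`, `level`, `call`.
#' @examples
#' sim <- generate_survey(synthetic_config(seed = 7))
#' fit <- equigap(anc4 ~ wealth_quintile + residence, sim$records,
#'                weights = "weight", strata = "stratum_id",
#'                cluster = "cluster_id", dimensions = synthetic_dimensions())
#' coef(fit)
#' @export
equigap <- function(formula, data, weights = NULL, strata = NULL,
                    cluster = NULL, dimensions = NULL, level = 0.95,
                    population = c("unweighted", "weighted"),
                    suppress_below = 25,
                    cov_method = c("share", "independent")) {
  population <- match.arg(population)
  cov_method <- match.arg(cov_method)
  stopifnot(inherits(formula, "formula"), length(formula) == 3L)
  outcome_var <- all.vars(formula[[2L]])
  dim_vars <- all.vars(formula[[3L]])
  if (length(outcome_var) != 1L || length(dim_vars) < 1L)
    stop("formula must be outcome ~ dim1 + dim2 + ...", call. = FALSE)

  col_or_vec <- function(x, default) {
    if (is.null(x)) return(default)
    if (is.character(x) && length(x) == 1L) {
      if (!x %in% names(data)) stop("column '", x, "' not found", call. = FALSE)
      data[[x]]
    } else {
      if (length(x) != nrow(data))
        stop("design vector length does not match data", call. = FALSE)
      x
    }
  }
  records <- data.frame(
    outcome = data[[outcome_var]],
    weight = col_or_vec(weights, rep(1, nrow(data))),
    stratum_id = as.character(col_or_vec(strata, rep("1", nrow(data)))),
    cluster_id = as.character(col_or_vec(cluster,
                                         as.character(seq_len(nrow(data))))),
    stringsAsFactors = FALSE)
  for (v in dim_vars) {
    if (!v %in% names(data)) stop("stratifier column '", v, "' not found",
                                  call. = FALSE)
    records[[v]] <- data[[v]]
  }
  check_records(records, dim_vars)

  specs <- lapply(dim_vars, function(v) {
    if (!is.null(dimensions) && v %in% names(dimensions)) {
      sp <- dimensions[[v]]
      stopifnot(inherits(sp, "dimension_spec"))
      sp
    } else infer_dimension(v, data[[v]])
  })
  names(specs) <- dim_vars

  nat <- national_average(records, level, population)
  disagg <- do.call(rbind, lapply(specs, function(sp)
    weighted_prevalence(records, sp, level, population, suppress_below)))
  row.names(disagg) <- NULL
  class(disagg) <- c("subgroup_estimates", "data.frame")
  measures <- do.call(rbind, lapply(specs, function(sp)
    compute_measures(disagg[disagg$dimension == sp$name, , drop = FALSE],
                     nat, sp, level, cov_method)))
  row.names(measures) <- NULL
  class(measures) <- c("ineq_measures", "data.frame")

  structure(list(disaggregation = disagg, national = nat,
                 measures = measures, dimensions = specs, level = level,
                 indicator = outcome_var, call = match.call()),
            class = "equigap")
}

#' Fit a health-inequality analysis from a published subgroup table
#'
#' Builds the same `"equigap"` object as [equigap()], but from
#' already-summarized subgroup rows (estimate, 95\% CI, population) plus a
#' national-average row -- the form in which published reports disseminate
#' disaggregated coverage. Subgroup standard errors are back-derived from
#' the printed intervals; when the national row prints no interval, the
#' national SE needed by the PAR/PAF intervals is rebuilt per dimension from
#' the subgroup SEs and population shares.
#'
#' @param subgroups data frame with `dimension, subgroup, estimate,
#'   ci_lower, ci_upper, population` (no national row), or a
#'   `subgroup_estimates` frame.
#' @param national list with at least `estimate` and `population` (and
#'   optionally `se`) for the national average, or a `national_average`.
#' @param dimensions named list of [dimension_spec()] keyed by dimension
#'   name; defaults to [angola_dimensions()] when all dimension names match.
#' @param level confidence level of the published intervals, default 0.95.
#' @param cov_method see [ineq_par()].
#' @param indicator indicator label for printing, default `"coverage"`.
#' @return an object of class `"equigap"`.
#' @examples
#' tab <- angola_anc4_2015()
#' fit <- equigap_published(tab$subgroups, tab$national)
#' summary(fit)
#' @export
equigap_published <- function(subgroups, national, dimensions = NULL,
                              level = 0.95,
                              cov_method = c("share", "independent"),
                              indicator = "coverage") {
  cov_method <- match.arg(cov_method)
  if (!inherits(subgroups, "subgroup_estimates"))
    subgroups <- summaries_from_published(subgroups, level)
  if (!inherits(national, "national_average")) {
    national <- structure(list(
      estimate = national$estimate,
      se = if (!is.null(national$se)) national$se else NA_real_,
      ci_lower = if (!is.null(national$ci_lower)) national$ci_lower else NA_real_,
      ci_upper = if (!is.null(national$ci_upper)) national$ci_upper else NA_real_,
      population = national$population), class = "national_average")
  }
  dim_names <- unique(subgroups$dimension)
  if (is.null(dimensions)) {
    ang <- angola_dimensions()
    if (all(dim_names %in% names(ang))) dimensions <- ang
    else dimensions <- lapply(setNames(dim_names, dim_names), function(d)
      infer_dimension(d, subgroups$subgroup[subgroups$dimension == d]))
  }
  miss <- setdiff(dim_names, names(dimensions))
  if (length(miss))
    stop("no dimension_spec for: ", paste(miss, collapse = ", "),
         call. = FALSE)
  measures <- do.call(rbind, lapply(dim_names, function(d)
    compute_measures(subgroups[subgroups$dimension == d, , drop = FALSE],
                     national, dimensions[[d]], level, cov_method)))
  row.names(measures) <- NULL
  class(measures) <- c("ineq_measures", "data.frame")
  structure(list(disaggregation = subgroups, national = national,
                 measures = measures, dimensions = dimensions[dim_names],
                 level = level, indicator = indicator, call = match.call()),
            class = "equigap")
}

#' @export
print.equigap <- function(x, ...) {
  cat("Health-inequality analysis of '", x$indicator, "'\n", sep = "")
  cat(sprintf("National average: %.2f%%", x$national$estimate))
  if (!is.na(x$national$se))
    cat(sprintf(" (SE %.3f)", x$national$se))
  cat("\nDimensions: ", paste(names(x$dimensions), collapse = ", "),
      "\n", sep = "")
  cat("Summary measures (", nrow(x$measures), " rows): ",
      "use summary() for the full tables\n", sep = "")
  invisible(x)
}

#' @export
summary.equigap <- function(object, digits = 2, ...) {
  structure(list(fit = object, digits = digits), class = "summary.equigap")
}

#' @export
print.summary.equigap <- function(x, ...) {
  fit <- x$fit
  d <- x$digits
  cat("Survey-weighted disaggregation of '", fit$indicator, "' (%)\n\n",
      sep = "")
  dis <- fit$disaggregation
  dis$estimate <- round(dis$estimate, d)
  dis$ci_lower <- round(dis$ci_lower, d)
  dis$ci_upper <- round(dis$ci_upper, d)
  print(dis[, c("dimension", "subgroup", "estimate", "ci_lower",
                "ci_upper", "population")], row.names = FALSE)
  cat(sprintf("\nNational average: %.4f%%\n", fit$national$estimate))
  cat("\nSummary measures of inequality (95% UI)\n\n")
  m <- fit$measures
  m$estimate <- round(m$estimate, d)
  m$ui_lower <- round(m$ui_lower, d)
  m$ui_upper <- round(m$ui_upper, d)
  print(m[, c("dimension", "measure", "estimate", "ui_lower", "ui_upper",
              "significant")], row.names = FALSE)
  invisible(x)
}

#' Extract summary-measure estimates
#'
#' @param object an `"equigap"` fit.
#' @param ... ignored.
#' @return named numeric vector, names `dimension_measure`
#'   (e.g. `economic_status_D`).
#' @export
coef.equigap <- function(object, ...) {
  m <- object$measures
  setNames(m$estimate, paste(m$dimension, m$measure, sep = "_"))
}

#' Uncertainty intervals of the summary measures
#'
#' @param object an `"equigap"` fit.
#' @param parm optional subset of `dimension_measure` names.
#' @param level ignored (intervals are computed at fit time).
#' @param ... ignored.
#' @return two-column matrix of lower/upper UI bounds.
#' @export
confint.equigap <- function(object, parm, level, ...) {
  m <- object$measures
  out <- cbind(lower = m$ui_lower, upper = m$ui_upper)
  rownames(out) <- paste(m$dimension, m$measure, sep = "_")
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}
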