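## The four WHO-style summary measures of inequality across the subgroups of
## one dimension: Difference (D), Ratio (R), Population Attributable Risk
## (PAR) and Population Attributable Fraction (PAF), each with a 95%
## uncertainty interval (UI) and a significance call (UI excludes 0, or 1
## for R).

measure_row <- function(dimension, measure, estimate, ui_lower, ui_upper,
                        reference, comparison = NA_character_,
                        flag = NA_character_) {
  null_value <- if (measure == "R") 1 else 0
  data.frame(
    dimension = dimension, measure = measure, estimate = estimate,
    ui_lower = ui_lower, ui_upper = ui_upper,
    reference = reference, comparison = comparison,
    significant = ui_lower > null_value || ui_upper < null_value,
    flag = flag, stringsAsFactors = FALSE)
}

#' Select reference and comparison subgroups for a dimension
#'
#' For ordered or binary dimensions the reference is the a-priori advantaged
#' category and the comparison the opposite extreme of the category ordering
#' (richest vs poorest, secondary+ vs no education, urban vs rural) --
#' intermediate categories are skipped by the simple measures. For
#' non-ordered dimensions (region) the reference is the subgroup with the
#' highest estimate and the comparison the one with the lowest; ties are
#' broken by category-list order and flagged.
#'
#' @param estimates a `subgroup_estimates` data frame for the dimension.
#' @param dimension the matching [dimension_spec()].
#' @return list with `reference`, `comparison` (category labels) and
#'   `tie` (logical: a tie was broken by list order).
#' @export
select_contrast <- function(estimates, dimension) {
  stopifnot(inherits(dimension, "dimension_spec"))
  est <- estimates[!isTRUE_vec(estimates$suppressed), , drop = FALSE]
  if (nrow(est) < 2L)
    stop("dimension '", dimension$name,
         "' has fewer than 2 non-suppressed subgroups", call. = FALSE)
  if (dimension$semantics %in% c("ordered", "binary")) {
    ref <- dimension$advantaged_end
    ends <- dimension$categories[c(1L, length(dimension$categories))]
    comp <- setdiff(ends, ref)[1L]
    if (!all(c(ref, comp) %in% est$subgroup))
      stop("extreme categories of '", dimension$name,
           "' are missing or suppressed", call. = FALSE)
    list(reference = ref, comparison = comp, tie = FALSE)
  } else {
    # rank by estimate; order within ties follows the category list
    ord <- match(est$subgroup, dimension$categories)
    est <- est[order(ord), , drop = FALSE]
    hi <- which(est$estimate == max(est$estimate))
    lo <- which(est$estimate == min(est$estimate))
    list(reference = est$subgroup[hi[1L]],
         comparison = est$subgroup[lo[1L]],
         tie = length(hi) > 1L || length(lo) > 1L)
  }
}

isTRUE_vec <- function(x) if (is.null(x)) FALSE else x %in% TRUE

# locate one subgroup row
subgroup_row <- function(estimates, label) {
  i <- which(estimates$subgroup == label)
  if (length(i) != 1L)
    stop("subgroup '", label, "' not found exactly once", call. = FALSE)
  estimates[i, , drop = FALSE]
}

require_se <- function(row) {
  if (is.na(row$se))
    stop("missing standard error for subgroup '", row$subgroup, "'",
         call. = FALSE)
  row$se
}

#' Difference measure (D)
#'
#' Reference-subgroup coverage minus comparison-subgroup coverage, in
#' percentage points. The UI treats the two subgroups as independent:
#' D +/- z * sqrt(se_ref^2 + se_comp^2). D = 0 means no inequality.
#'
#' @param reference,comparison single rows of a `subgroup_estimates` frame.
#' @param level confidence level, default 0.95.
#' @return one-row measures data frame.
#' @export
ineq_difference <- function(reference, comparison, level = 0.95) {
  z <- z_for_level(level)
  se <- sqrt(require_se(reference)^2 + require_se(comparison)^2)
  d <- reference$estimate - comparison$estimate
  measure_row(reference$dimension, "D", d, d - z * se, d + z * se,
              reference$subgroup, comparison$subgroup)
}

#' Ratio measure (R)
#'
#' Reference-subgroup coverage divided by comparison-subgroup coverage
#' (unitless). The UI is built on the log scale by the delta method,
#' se(log R) = sqrt((se_ref/ref)^2 + (se_comp/comp)^2), then exponentiated.
#' R = 1 means no inequality.
#'
#' @inheritParams ineq_difference
#' @return one-row measures data frame.
#' @export
ineq_ratio <- function(reference, comparison, level = 0.95) {
  if (comparison$estimate <= 0)
    stop("ratio undefined: comparison subgroup '", comparison$subgroup,
         "' has zero coverage", call. = FALSE)
  z <- z_for_level(level)
  r <- reference$estimate / comparison$estimate
  sl <- sqrt((require_se(reference) / reference$estimate)^2 +
             (require_se(comparison) / comparison$estimate)^2)
  measure_row(reference$dimension, "R", r,
              r * exp(-z * sl), r * exp(z * sl),
              reference$subgroup, comparison$subgroup)
}

#' Population attributable risk (PAR)
#'
#' Reference-subgroup coverage minus the national average mu, in percentage
#' points: the absolute gain in national coverage if every subgroup attained
#' the reference level. For a favourable indicator the reference is the
#' best-off subgroup, so a negative PAR can only arise from estimation
#' noise; negative values are truncated to 0 and flagged.
#'
#' The UI uses the delta method on (ref - mu). Because the reference
#' subgroup is part of the national average the two estimates are positively
#' correlated; by default Cov(ref, mu) is approximated by
#' share_ref * Var(ref), where share_ref is the reference subgroup's
#' population share (`cov_method = "share"`). `cov_method = "independent"`
#' ignores the covariance (a wider interval).
#'
#' @param reference single row of a `subgroup_estimates` frame.
#' @param mu a `national_average` object (or list with `estimate`, `se`).
#' @param share_ref population share (0-1) of the reference subgroup within
#'   the national denominator.
#' @param cov_method `"share"` (default) or `"independent"`.
#' @param level confidence level, default 0.95.
#' @return one-row measures data frame; `flag` is `"truncated"` when a
#'   negative estimate was raised to 0.
#' @export
ineq_par <- function(reference, mu, share_ref,
                     cov_method = c("share", "independent"), level = 0.95) {
  cov_method <- match.arg(cov_method)
  z <- z_for_level(level)
  se_r <- require_se(reference)
  if (is.na(mu$se))
    stop("missing standard error for the national average", call. = FALSE)
  cv <- if (cov_method == "share") share_ref * se_r^2 else 0
  v <- se_r^2 + mu$se^2 - 2 * cv
  se <- sqrt(max(v, 0))
  est <- reference$estimate - mu$estimate
  lo <- est - z * se
  hi <- est + z * se
  flag <- NA_character_
  if (est < 0) {
    est <- 0
    lo <- min(lo, 0)
    hi <- max(hi, 0)
    flag <- "truncated"
  }
  measure_row(reference$dimension, "PAR", est, lo, hi,
              reference$subgroup, flag = flag)
}

#' Population attributable fraction (PAF)
#'
#' PAR rescaled to a percentage of current national coverage:
#' PAF = 100 * PAR / mu. The UI bounds are the PAR bounds scaled by the same
#' factor 100/mu, so the PAR/PAF coupling holds exactly by construction.
#'
#' @param par_result one-row measures frame produced by [ineq_par()].
#' @param mu a `national_average` object; `mu$estimate` must be > 0.
#' @return one-row measures data frame.
#' @export
ineq_paf <- function(par_result, mu) {
  if (!isTRUE(mu$estimate > 0))
    stop("PAF undefined: national average must be positive", call. = FALSE)
  f <- 100 / mu$estimate
  measure_row(par_result$dimension, "PAF", f * par_result$estimate,
              f * par_result$ui_lower, f * par_result$ui_upper,
              par_result$reference, flag = par_result$flag)
}

#' Does a measure's uncertainty interval exclude its null value?
#'
#' Inequality is called statistically significant when the 95\% UI excludes
#' the no-inequality value: 0 for D, PAR and PAF; 1 for R.
#'
#' @param result one-row measures data frame.
#' @return logical.
#' @export
is_significant <- function(result) {
  null_value <- if (result$measure == "R") 1 else 0
  result$ui_lower > null_value || result$ui_upper < null_value
}

#' All four summary measures for one dimension
#'
#' Selects the reference/comparison contrast per the dimension's semantics
#' and computes D, R, PAR and PAF with uncertainty intervals.
#'
#' @param estimates `subgroup_estimates` frame for the dimension.
#' @param national `national_average` object (mu).
#' @param dimension the [dimension_spec()].
#' @param level confidence level, default 0.95.
#' @param cov_method covariance handling for the PAR interval, see
#'   [ineq_par()].
#' @return measures data frame with four rows (D, R, PAR, PAF), columns
#'   `dimension, measure, estimate, ui_lower, ui_upper, reference,
#'   comparison, significant, flag`.
#' @export
compute_measures <- function(estimates, national, dimension, level = 0.95,
                             cov_method = c("share", "independent")) {
  cov_method <- match.arg(cov_method)
  ct <- select_contrast(estimates, dimension)
  ref <- subgroup_row(estimates, ct$reference)
  comp <- subgroup_row(estimates, ct$comparison)
  pop_total <- if (!is.null(national$population) &&
                   is.finite(national$population) && national$population > 0)
    national$population else sum(estimates$population)
  share_ref <- ref$population / pop_total
  # national SE rebuilt from this dimension's subgroups when unavailable
  # (published national rows print no interval): Var(mu) = sum share_g^2 Var_g
  mu <- national
  if (is.na(mu$se)) {
    shares <- estimates$population / pop_total
    mu$se <- sqrt(sum(shares^2 * estimates$se^2))
  }
  d <- ineq_difference(ref, comp, level)
  r <- ineq_ratio(ref, comp, level)
  pr <- ineq_par(ref, mu, share_ref, cov_method, level)
  pf <- ineq_paf(pr, mu)
  out <- rbind(d, r, pr, pf)
  if (ct$tie) out$flag[is.na(out$flag)] <- "tie"
  row.names(out) <- NULL
  class(out) <- c("ineq_measures", "data.frame")
  out
}
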