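## File-in / file-out orchestration: typed CSV readers with row-level
## validation, the end-to-end pipeline (disaggregation + measures +
## composition tables), and the packaged benchmark reproduction.

#' Read unit-level survey records from CSV
#'
#' Expects columns `outcome` (or `anc4`, copied to `outcome`), `weight`,
#' `stratum_id`, `cluster_id` and any stratifier columns. Fails with the
#' offending row numbers on non-binary outcomes or non-positive weights.
#'
#' @param path CSV file path.
#' @return data frame of validated records; the row count is reported via
#'   `message()`.
#' @export
read_unit_records <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!"outcome" %in% names(df) && "anc4" %in% names(df))
    df$outcome <- df$anc4
  check_records(df)
  for (v in intersect(c("stratum_id", "cluster_id", "wealth_quintile",
                        "region", "residence", "education"), names(df)))
    df[[v]] <- as.character(df[[v]])
  message("read ", nrow(df), " unit-level records from ", path)
  df
}

#' Read a subgroup-summary table from CSV
#'
#' Expects the published-table schema `dimension, subgroup, estimate,
#' ci_lower, ci_upper, population` with exactly one national-average row
#' (dimension `"national_average"`), which the population-attributable
#' measures require. Duplicate subgroup labels within a dimension are an
#' error.
#'
#' @param path CSV file path.
#' @param level confidence level of the published intervals, default 0.95.
#' @return list with `subgroups` (a `subgroup_estimates` frame, SEs
#'   back-derived) and `national` (a `national_average`).
#' @export
read_subgroup_summaries <- function(path, level = 0.95) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("dimension", "subgroup", "estimate", "ci_lower", "ci_upper",
            "population")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("subgroup summary file missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  is_nat <- df$dimension == "national_average"
  if (sum(is_nat) != 1L)
    stop("expected exactly one national_average row (found ", sum(is_nat),
         "); PAR/PAF need the national average", call. = FALSE)
  sub <- df[!is_nat, , drop = FALSE]
  dup <- duplicated(sub[, c("dimension", "subgroup")])
  if (any(dup))
    stop("duplicated subgroup within a dimension: ",
         paste(unique(sub$subgroup[dup]), collapse = ", "), call. = FALSE)
  nat_row <- df[is_nat, , drop = FALSE]
  z <- z_for_level(level)
  nat_se <- if (is.finite(nat_row$ci_lower) && is.finite(nat_row$ci_upper))
    (nat_row$ci_upper - nat_row$ci_lower) / (2 * z) else NA_real_
  national <- structure(list(
    estimate = nat_row$estimate, se = nat_se,
    ci_lower = nat_row$ci_lower, ci_upper = nat_row$ci_upper,
    population = nat_row$population), class = "national_average")
  list(subgroups = summaries_from_published(sub, level),
       national = national)
}

#' Write a subgroup-summary table to CSV
#'
#' Inverse of [read_subgroup_summaries()]: the published-table schema with
#' the national row appended.
#' @param subgroups a `subgroup_estimates` frame.
#' @param national a `national_average`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_subgroup_summaries <- function(subgroups, national, path) {
  nat <- data.frame(dimension = "national_average",
                    subgroup = "National average",
                    estimate = national$estimate,
                    ci_lower = national$ci_lower,
                    ci_upper = national$ci_upper,
                    population = national$population,
                    stringsAsFactors = FALSE)
  cols <- c("dimension", "subgroup", "estimate", "ci_lower", "ci_upper",
            "population")
  write.csv(rbind(subgroups[, cols], nat), path, row.names = FALSE,
            quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

# stable hash of a configuration for run logging
config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  dput(cfg, file = f)
  unname(tools::md5sum(f))
}

#' Run the full inequality pipeline on a file
#'
#' Reads unit-level records or a subgroup-summary table, fits the analysis
#' via [equigap()] / [equigap_published()], and returns (optionally writes)
#' three tidy tables: the disaggregation (one row per subgroup), the
#' measures table (4 measures per dimension, with UIs and significance) and
#' a composition table (each subgroup's share of the total population, in
#' percent). Output column order is fixed for diff-based testing; identical
#' input and configuration produce byte-identical files.
#'
#' @param input path to the input CSV.
#' @param level_of_input `"unit"` or `"subgroup"`.
#' @param dimensions named list of [dimension_spec()]; for unit-level input
#'   defaults to [synthetic_dimensions()] entries present in the file, for
#'   subgroup input to [angola_dimensions()] when the names match.
#' @param indicator outcome column for unit-level input, default `"anc4"`.
#' @param level confidence level, default 0.95.
#' @param suppress_below suppression threshold for unit-level input.
#' @param population `"unweighted"` or `"weighted"` population reporting.
#' @param cov_method see [ineq_par()].
#' @param out_dir if non-NULL, write `disaggregation.csv`, `measures.csv`,
#'   `composition.csv` there.
#' @return list of class `"equigap_run"`: `disaggregation`, `measures`,
#'   `composition` data frames and the underlying `fit`.
#' @export
run_pipeline <- function(input, level_of_input = c("unit", "subgroup"),
                         dimensions = NULL, indicator = "anc4",
                         level = 0.95, suppress_below = 25,
                         population = c("unweighted", "weighted"),
                         cov_method = c("share", "independent"),
                         out_dir = NULL) {
  level_of_input <- match.arg(level_of_input)
  population <- match.arg(population)
  cov_method <- match.arg(cov_method)
  cfg <- list(input = basename(input), level_of_input = level_of_input,
              indicator = indicator, level = level,
              suppress_below = suppress_below, population = population,
              cov_method = cov_method)
  message("run config hash: ", config_hash(cfg))

  t0 <- proc.time()[["elapsed"]]
  fit <- if (level_of_input == "unit") {
    records <- tryCatch(read_unit_records(input), error = function(e)
      stop("stage read_unit_records: ", conditionMessage(e), call. = FALSE))
    if (is.null(dimensions)) {
      present <- intersect(names(synthetic_dimensions()), names(records))
      present <- setdiff(present, indicator)
      if (!length(present))
        stop("stage configure: no stratifier columns found", call. = FALSE)
      dimensions <- synthetic_dimensions()[present]
      for (v in present) {  # data with other category labels: infer instead
        vals <- unique(as.character(records[[v]]))
        if (!all(vals %in% dimensions[[v]]$categories))
          dimensions[[v]] <- infer_dimension(v, records[[v]])
      }
    }
    fml <- stats::as.formula(paste(
      indicator, "~", paste(names(dimensions), collapse = "+")))
    tryCatch(
      equigap(fml, records, weights = "weight", strata = "stratum_id",
              cluster = "cluster_id", dimensions = dimensions,
              level = level, population = population,
              suppress_below = suppress_below, cov_method = cov_method),
      error = function(e) stop("stage estimation: ", conditionMessage(e),
                               call. = FALSE))
  } else {
    tab <- tryCatch(read_subgroup_summaries(input, level),
                    error = function(e) stop("stage read_subgroup_summaries: ",
                                             conditionMessage(e), call. = FALSE))
    tryCatch(
      equigap_published(tab$subgroups, tab$national, dimensions, level,
                        cov_method, indicator = indicator),
      error = function(e) stop("stage measures: ", conditionMessage(e),
                               call. = FALSE))
  }

  dis <- fit$disaggregation[, c("dimension", "subgroup", "estimate",
                                "ci_lower", "ci_upper", "population",
                                "suppressed")]
  if (any(dis$suppressed))
    warning("suppressed subgroups (n below threshold): ",
            paste(dis$subgroup[dis$suppressed], collapse = ", "),
            call. = FALSE)
  mea <- fit$measures[, c("dimension", "measure", "estimate", "ui_lower",
                          "ui_upper", "reference", "comparison",
                          "significant", "flag")]
  comp <- do.call(rbind, lapply(split(dis, dis$dimension), function(d)
    data.frame(dimension = d$dimension, subgroup = d$subgroup,
               share = 100 * d$population / sum(d$population),
               stringsAsFactors = FALSE)))
  row.names(comp) <- NULL
  message(sprintf("pipeline finished in %.2fs: %d subgroups, %d measures",
                  proc.time()[["elapsed"]] - t0, nrow(dis), nrow(mea)))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(dis, file.path(out_dir, "disaggregation.csv"),
              row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
    write.csv(mea, file.path(out_dir, "measures.csv"),
              row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
    write.csv(comp, file.path(out_dir, "composition.csv"),
              row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  }
  structure(list(disaggregation = dis, measures = mea, composition = comp,
                 fit = fit), class = "equigap_run")
}

#' Reproduce the published Angola 2015-16 benchmark
#'
#' Recomputes all 16 summary-measure estimates (4 dimensions x D/R/PAR/PAF)
#' from the packaged published subgroup table -- printed estimates plus the
#' printed national average 61.4464\% -- and compares them with the packaged
#' published measure values.
#'
#' @param tolerance maximum |computed - published| allowed per measure, on
#'   the percentage-point scale for D/PAR/PAF and the ratio scale for R.
#'   Default 0.02, which absorbs the rounding of the printed inputs.
#' @return data frame of class `"equigap_benchmark"`: `dimension, measure,
#'   computed, published, abs_diff, pass`; attribute `pass` is `TRUE` when
#'   all rows pass.
#' @examples
#' rep <- reproduce_benchmark()
#' attr(rep, "pass")
#' @export
reproduce_benchmark <- function(tolerance = 0.02) {
  tab <- angola_anc4_2015()
  fit <- equigap_published(tab$subgroups, tab$national,
                           dimensions = angola_dimensions(),
                           indicator = "anc4")
  pub <- angola_anc4_2015_measures()
  m <- fit$measures
  key <- paste(pub$dimension, pub$measure)
  idx <- match(key, paste(m$dimension, m$measure))
  out <- data.frame(dimension = pub$dimension, measure = pub$measure,
                    computed = m$estimate[idx], published = pub$estimate,
                    abs_diff = abs(m$estimate[idx] - pub$estimate),
                    stringsAsFactors = FALSE)
  out$pass <- out$abs_diff <= tolerance
  attr(out, "pass") <- all(out$pass)
  attr(out, "tolerance") <- tolerance
  class(out) <- c("equigap_benchmark", "data.frame")
  out
}

#' @export
print.equigap_benchmark <- function(x, ...) {
  cat("Benchmark: recomputed vs published summary measures\n")
  df <- as.data.frame(x)
  df$computed <- round(df$computed, 4)
  df$abs_diff <- round(df$abs_diff, 4)
  print(df, row.names = FALSE)
  cat(if (attr(x, "pass")) "\nAll measures within tolerance "
      else "\nTOLERANCE EXCEEDED at ",
      attr(x, "tolerance"), "\n", sep = "")
  invisible(x)
}
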