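#' Define an equity stratifier (dimension of inequality)
#'
#' A dimension describes one way of partitioning the surveyed population:
#' its ordered category list, whether the ordering carries an a-priori
#' advantage ranking, and which end of an ordered/binary dimension is the
#' most advantaged. The semantics drive reference-group selection for the
#' summary measures: for `ordered` and `binary` dimensions the reference is
#' the advantaged category and the comparison is the opposite extreme
#' (richest vs poorest, secondary+ vs no education, urban vs rural); for
#' `non_ordered` dimensions (e.g. subnational region) the reference is the
#' best-performing subgroup and the comparison the worst-performing one.
#'
#' @param name dimension label, e.g. `"economic_status"`.
#' @param categories character vector of category labels, in display order
#'   (for ordered dimensions: from most disadvantaged to most advantaged or
#'   vice versa -- `advantaged_end` disambiguates).
#' @param semantics one of `"ordered"`, `"binary"`, `"non_ordered"`.
#' @param advantaged_end the category that is a priori most advantaged.
#'   Required for ordered/binary dimensions, must be `NULL` for non-ordered.
#' @return an object of class `"dimension_spec"`.
#' @examples
#' dimension_spec("residence", c("rural", "urban"), "binary", "urban")
#' @export
dimension_spec <- function(name, categories,
                           semantics = c("ordered", "binary", "non_ordered"),
                           advantaged_end = NULL) {
  semantics <- match.arg(semantics)
  categories <- as.character(categories)
  if (length(categories) < 2L)
    stop("dimension '", name, "' needs at least 2 categories", call. = FALSE)
  if (anyDuplicated(categories))
    stop("dimension '", name, "' has duplicated categories", call. = FALSE)
  if (semantics == "binary" && length(categories) != 2L)
    stop("binary dimension '", name, "' must have exactly 2 categories",
         call. = FALSE)
  if (semantics == "non_ordered") {
    if (!is.null(advantaged_end))
      stop("non_ordered dimension '", name,
           "' must not declare an advantaged end", call. = FALSE)
  } else {
    if (is.null(advantaged_end) || !advantaged_end %in% categories)
      stop("dimension '", name,
           "' (", semantics, ") needs advantaged_end among its categories",
           call. = FALSE)
  }
  structure(
    list(name = as.character(name), categories = categories,
         semantics = semantics, advantaged_end = advantaged_end),
    class = "dimension_spec")
}

#' @export
print.dimension_spec <- function(x, ...) {
  cat("<dimension_spec> ", x$name, " [", x$semantics, "]\n", sep = "")
  cat("  categories: ", paste(x$categories, collapse = ", "), "\n", sep = "")
  if (!is.null(x$advantaged_end))
    cat("  advantaged: ", x$advantaged_end, "\n", sep = "")
  invisible(x)
}

#' Names of the 18 Angola subnational regions
#'
#' Region labels as used in the 2015-16 Angola DHS reporting.
#' @return character vector of length 18.
#' @export
angola_regions <- function() {
  c("Cabinda", "Zaire", "Uige", "Luanda", "Cuanza Norte", "Cuanza Sul",
    "Malanje", "Lunda Norte", "Benguela", "Huambo", "Bie", "Moxico",
    "Cuando Cubango", "Namibe", "Huila", "Cunene", "Lunda Sul", "Bengo")
}

#' The four equity stratifiers of the packaged Angola ANC4+ analysis
#'
#' Wealth quintile (ordered, richest advantaged), maternal education
#' (ordered, secondary+ advantaged), place of residence (binary, urban
#' advantaged) and subnational region (non-ordered; the reference is the
#' region with the highest coverage). Category labels match the packaged
#' published-table fixture.
#'
#' @return named list of [dimension_spec()] objects.
#' @export
angola_dimensions <- function() {
  list(
    economic_status = dimension_spec(
      "economic_status",
      c("Quintile 1 (poorest)", "Quintile 2", "Quintile 3", "Quintile 4",
        "Quintile 5 (richest)"),
      "ordered", "Quintile 5 (richest)"),
    education = dimension_spec(
      "education",
      c("No education", "Primary school", "Secondary school +"),
      "ordered", "Secondary school +"),
    residence = dimension_spec(
      "residence", c("Rural", "Urban"), "binary", "Urban"),
    region = dimension_spec(
      "region", angola_regions(), "non_ordered"))
}

#' Dimensions matching the synthetic-survey generator's columns
#'
#' @return named list of [dimension_spec()] objects whose names are the
#'   stratifier columns written by [generate_survey()].
#' @export
synthetic_dimensions <- function() {
  list(
    wealth_quintile = dimension_spec(
      "wealth_quintile", as.character(1:5), "ordered", "5"),
    education = dimension_spec(
      "education", c("none", "primary", "secondary+"), "ordered",
      "secondary+"),
    residence = dimension_spec(
      "residence", c("rural", "urban"), "binary", "urban"),
    region = dimension_spec("region", angola_regions(), "non_ordered"))
}

# Fallback inference when equigap() is given no specs: ordered factors keep
# their ordering with the last level advantaged; everything else non-ordered,
# except two-level ordered-looking columns are left non_ordered too (the
# caller should be explicit when advantage matters).
infer_dimension <- function(name, values) {
  if (is.ordered(values)) {
    lev <- levels(values)
    dimension_spec(name, lev,
                   if (length(lev) == 2L) "binary" else "ordered",
                   advantaged_end = lev[length(lev)])
  } else {
    lev <- if (is.factor(values)) levels(values) else sort(unique(as.character(values)))
    dimension_spec(name, lev, "non_ordered")
  }
}
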