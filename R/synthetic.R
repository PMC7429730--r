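## DHS-like synthetic survey generator with known truth.
##
## Emulates a stratified two-stage cluster sample: strata are region x
## residence, clusters (PSUs) are nested in strata, women are nested in
## clusters. The binary outcome follows a logistic model with additive
## region / residence / wealth / education effects plus an optional
## cluster-level random intercept (intra-cluster correlation). Sampling
## weights are inverse stratum selection probabilities times lognormal
## noise. The implied truth table (cell probabilities and population
## shares) is returned alongside the records so estimators can be validated
## against known estimands.

# default per-region population shares, proportional to the published
# Angola 2015-16 analysis denominators
angola_region_share <- function() {
  pop <- c(191, 186, 460, 2696, 111, 676, 323, 247, 754, 650, 414, 167,
           164, 108, 763, 321, 163, 92)
  setNames(pop / sum(pop), angola_regions())
}

angola_urban_share <- function() {
  setNames(c(0.80, 0.55, 0.35, 0.97, 0.40, 0.30, 0.40, 0.45, 0.60, 0.50,
             0.35, 0.40, 0.35, 0.75, 0.40, 0.35, 0.50, 0.45),
           angola_regions())
}

default_region_effects <- function() {
  setNames(c(0.30, 0.80, -0.50, 0.90, 0.00, -0.90, 0.00, -0.50, 0.10,
             0.30, -0.10, -0.50, -0.40, 0.40, -0.20, 0.20, 0.20, 0.25),
           angola_regions())
}

#' Configuration for the synthetic survey generator
#'
#' The defaults describe an Angola-like design: 18 regions with population
#' shares proportional to the published analysis denominators, strata formed
#' by region x urban/rural (36 strata), 10 clusters per stratum and 24 women
#' per cluster (8,640 women, close to the ~8,500 of the emulated analysis).
#' Wealth and education are drawn from per-residence category probabilities
#' (urban skews rich/educated, so stratifiers are correlated as in real DHS
#' data); the outcome model's default effects produce coverage gradients of
#' the magnitude seen in the published tables.
#'
#' @param regions character vector of region labels.
#' @param region_share named population share per region (sums to 1).
#' @param urban_share_by_region named fraction urban per region.
#' @param n_clusters_per_stratum clusters (PSUs) per stratum; must be >= 2
#'   for variance estimability.
#' @param n_women_per_cluster women sampled per cluster.
#' @param intercept log-odds of the outcome for the baseline cell (rural,
#'   poorest quintile, no education, region effect 0).
#' @param wealth_effects,education_effects additive log-odds effects for
#'   wealth quintiles 1-5 and education none/primary/secondary+ (first
#'   element 0 by convention).
#' @param urban_effect additive log-odds effect of urban residence.
#' @param region_effects named additive log-odds effect per region.
#' @param wealth_probs_urban,wealth_probs_rural length-5 category
#'   probabilities for wealth quintile by residence.
#' @param education_probs_urban,education_probs_rural length-3 category
#'   probabilities for education by residence.
#' @param cluster_sd standard deviation of the cluster-level random
#'   intercept on the log-odds scale (0 = no intra-cluster correlation).
#' @param weight_dispersion sigma of the mean-1 lognormal noise multiplying
#'   the inverse-selection-probability base weight.
#' @param seed integer seed governing all draws.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(regions = angola_regions(),
                             region_share = angola_region_share(),
                             urban_share_by_region = angola_urban_share(),
                             n_clusters_per_stratum = 10L,
                             n_women_per_cluster = 24L,
                             intercept = -1.6,
                             wealth_effects = c(0, 0.38, 1.05, 1.85, 2.45),
                             education_effects = c(0, 0.7, 1.35),
                             urban_effect = 0.25,
                             region_effects = default_region_effects(),
                             wealth_probs_urban = c(0.08, 0.14, 0.20, 0.26, 0.32),
                             wealth_probs_rural = c(0.34, 0.27, 0.20, 0.13, 0.06),
                             education_probs_urban = c(0.14, 0.36, 0.50),
                             education_probs_rural = c(0.44, 0.41, 0.15),
                             cluster_sd = 0.3,
                             weight_dispersion = 0.3,
                             seed = 1L) {
  regions <- as.character(regions)
  if (is.null(names(region_share))) names(region_share) <- regions
  if (is.null(names(urban_share_by_region)))
    names(urban_share_by_region) <- regions
  if (is.null(names(region_effects))) names(region_effects) <- regions
  cfg <- list(regions = regions,
              region_share = region_share[regions],
              urban_share_by_region = urban_share_by_region[regions],
              n_clusters_per_stratum = as.integer(n_clusters_per_stratum),
              n_women_per_cluster = as.integer(n_women_per_cluster),
              intercept = intercept, wealth_effects = wealth_effects,
              education_effects = education_effects,
              urban_effect = urban_effect,
              region_effects = region_effects[regions],
              wealth_probs_urban = wealth_probs_urban,
              wealth_probs_rural = wealth_probs_rural,
              education_probs_urban = education_probs_urban,
              education_probs_rural = education_probs_rural,
              cluster_sd = cluster_sd,
              weight_dispersion = weight_dispersion,
              seed = as.integer(seed))
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  with(cfg, {
    if (length(regions) < 1L) stop("need at least one region", call. = FALSE)
    if (abs(sum(region_share) - 1) > 1e-8)
      stop("region_share must sum to 1", call. = FALSE)
    if (any(region_share <= 0)) stop("region shares must be positive", call. = FALSE)
    if (any(urban_share_by_region < 0 | urban_share_by_region > 1))
      stop("urban shares must lie in [0,1]", call. = FALSE)
    if (n_clusters_per_stratum < 2L) {
      s1 <- paste(regions[1L], "urban", sep = ":")
      stop("non-estimable design: stratum '", s1, "' (and every other ",
           "stratum) has fewer than 2 clusters", call. = FALSE)
    }
    if (n_women_per_cluster < 1L)
      stop("need at least 1 woman per cluster", call. = FALSE)
    stopifnot(length(wealth_effects) == 5L, length(education_effects) == 3L)
    for (p in list(wealth_probs_urban, wealth_probs_rural,
                   education_probs_urban, education_probs_rural))
      if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
        stop("category probabilities must be nonnegative and sum to 1",
             call. = FALSE)
    if (cluster_sd < 0 || weight_dispersion < 0)
      stop("dispersion parameters must be nonnegative", call. = FALSE)
    lp <- outer_linear_predictors(cfg)
    if (any(!is.finite(lp)))
      stop("outcome model produces non-finite log-odds", call. = FALSE)
  })
  invisible(cfg)
}

# linear predictor for every (region, residence, wealth, education) cell,
# as a vector aligned with the truth-table grid
truth_grid <- function(cfg) {
  expand.grid(education = c("none", "primary", "secondary+"),
              wealth_quintile = as.character(1:5),
              residence = c("rural", "urban"),
              region = cfg$regions,
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)[, 4:1]
}

outer_linear_predictors <- function(cfg) {
  g <- truth_grid(cfg)
  cfg$intercept +
    cfg$region_effects[g$region] +
    ifelse(g$residence == "urban", cfg$urban_effect, 0) +
    cfg$wealth_effects[as.integer(g$wealth_quintile)] +
    cfg$education_effects[match(g$education, c("none", "primary", "secondary+"))]
}

# marginal Bernoulli probability integrating out a N(0, sd) cluster
# intercept on the log-odds scale
marginal_prob <- function(lp, sd) {
  if (sd == 0) return(plogis(lp))
  vapply(lp, function(l)
    integrate(function(u) plogis(l + u) * dnorm(u, sd = sd),
              -Inf, Inf, rel.tol = 1e-9)$value,
    numeric(1))
}

#' True coverage table implied by a synthetic configuration
#'
#' Builds the full (region x residence x wealth x education) cell grid with
#' the marginal outcome probability of each cell (integrating out the
#' cluster random effect) and the cell's population share, plus the derived
#' true subgroup coverages and the true national average. These are the
#' estimands the survey estimators should recover.
#'
#' @param cfg a [synthetic_config()].
#' @return list of class `synthetic_truth`: `cells` (data frame with
#'   `region, residence, wealth_quintile, education, probability, share`),
#'   `subgroups` (data frame `dimension, subgroup, true_coverage` in
#'   percent) and `national_average` (percent).
#' @export
synthetic_truth <- function(cfg) {
  g <- truth_grid(cfg)
  g$probability <- marginal_prob(outer_linear_predictors(cfg),
                                 cfg$cluster_sd)
  ushare <- cfg$urban_share_by_region[g$region]
  res_share <- ifelse(g$residence == "urban", ushare, 1 - ushare)
  wp <- ifelse(g$residence == "urban",
               cfg$wealth_probs_urban[as.integer(g$wealth_quintile)],
               cfg$wealth_probs_rural[as.integer(g$wealth_quintile)])
  ei <- match(g$education, c("none", "primary", "secondary+"))
  ep <- ifelse(g$residence == "urban",
               cfg$education_probs_urban[ei], cfg$education_probs_rural[ei])
  g$share <- as.numeric(cfg$region_share[g$region] * res_share * wp * ep)
  subgroup_cov <- function(key) {
    agg <- rowsum(cbind(ps = g$share * g$probability, s = g$share), g[[key]],
                  reorder = FALSE)
    data.frame(dimension = key, subgroup = rownames(agg),
               true_coverage = 100 * agg[, "ps"] / agg[, "s"],
               stringsAsFactors = FALSE, row.names = NULL)
  }
  subs <- do.call(rbind, lapply(
    c("region", "residence", "wealth_quintile", "education"), subgroup_cov))
  structure(list(cells = g, subgroups = subs,
                 national_average = 100 * sum(g$share * g$probability)),
            class = "synthetic_truth")
}

#' True subgroup coverages for one dimension
#'
#' Convenience accessor on a [synthetic_truth()] object: the estimand that
#' [weighted_prevalence()] should recover for the given dimension.
#'
#' @param truth a `synthetic_truth` object.
#' @param dimension a [dimension_spec()] or a dimension name; must be one of
#'   `region`, `residence`, `wealth_quintile`, `education`.
#' @return data frame with `subgroup` and `true_coverage` (percent).
#' @export
truth_summary <- function(truth, dimension) {
  name <- if (inherits(dimension, "dimension_spec")) dimension$name
          else as.character(dimension)
  if (!name %in% unique(truth$subgroups$dimension))
    stop("unknown dimension '", name, "'", call. = FALSE)
  out <- truth$subgroups[truth$subgroups$dimension == name,
                         c("subgroup", "true_coverage")]
  row.names(out) <- NULL
  out
}

#' Generate a synthetic stratified two-stage cluster survey
#'
#' Draws one survey from the design described by `cfg`. Generator order (the
#' seed contract -- stable across releases): (1) cluster random intercepts,
#' stratum by stratum in region-major, urban-before-rural order; (2) per
#' woman, wealth quintile; (3) education; (4) outcome; (5) weight noise.
#' Weights are the stratum's inverse selection probability (population share
#' over sampled share) times mean-1 lognormal noise with sigma
#' `weight_dispersion`, normalized to mean 1 overall.
#'
#' The same configuration (including `seed`) always yields byte-identical
#' records.
#'
#' @param cfg a [synthetic_config()].
#' @return list with `records` (data frame: `woman_id, region, residence,
#'   wealth_quintile, education, anc4, weight, stratum_id, cluster_id`, plus
#'   `outcome` duplicating `anc4` for the estimation interface) and `truth`
#'   (a [synthetic_truth()] object).
#' @export
generate_survey <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  validate_synthetic_config(cfg)
  truth <- synthetic_truth(cfg)
  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(cfg$seed)

  strata <- expand.grid(residence = c("urban", "rural"),
                        region = cfg$regions,
                        KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)[, 2:1]
  nc <- cfg$n_clusters_per_stratum
  m <- cfg$n_women_per_cluster
  n_per_stratum <- nc * m
  H <- nrow(strata)
  n <- H * n_per_stratum

  region <- rep(strata$region, each = n_per_stratum)
  residence <- rep(strata$residence, each = n_per_stratum)
  stratum_id <- paste(region, residence, sep = ":")
  cluster_in_stratum <- rep(rep(seq_len(nc), each = m), times = H)
  cluster_id <- sprintf("%s:c%02d", stratum_id, cluster_in_stratum)

  # (1) cluster random intercepts
  u_cl <- rnorm(H * nc, 0, cfg$cluster_sd)
  u <- rep(u_cl, each = m)

  urban <- residence == "urban"
  # (2) wealth quintile via inverse-CDF draw against residence-specific probs
  cw_u <- cumsum(cfg$wealth_probs_urban)
  cw_r <- cumsum(cfg$wealth_probs_rural)
  rw <- runif(n)
  wealth <- ifelse(urban,
                   findInterval(rw, cw_u, left.open = TRUE) + 1L,
                   findInterval(rw, cw_r, left.open = TRUE) + 1L)
  wealth <- pmin(wealth, 5L)
  # (3) education
  ce_u <- cumsum(cfg$education_probs_urban)
  ce_r <- cumsum(cfg$education_probs_rural)
  re <- runif(n)
  edu_i <- ifelse(urban,
                  findInterval(re, ce_u, left.open = TRUE) + 1L,
                  findInterval(re, ce_r, left.open = TRUE) + 1L)
  edu_i <- pmin(edu_i, 3L)
  education <- c("none", "primary", "secondary+")[edu_i]

  lp <- cfg$intercept + cfg$region_effects[region] +
    ifelse(urban, cfg$urban_effect, 0) +
    cfg$wealth_effects[wealth] + cfg$education_effects[edu_i] + u
  # (4) outcome
  anc4 <- rbinom(n, 1L, plogis(lp))

  # base weight: stratum population share / stratum sample share
  ushare <- cfg$urban_share_by_region[region]
  pop_share <- as.numeric(cfg$region_share[region] *
                            ifelse(urban, ushare, 1 - ushare))
  base_w <- pop_share / (n_per_stratum / n)
  # (5) lognormal noise, mean 1
  sig <- cfg$weight_dispersion
  noise <- if (sig > 0) rlnorm(n, meanlog = -sig^2 / 2, sdlog = sig)
           else rep(1, n)
  weight <- base_w * noise
  weight <- weight / mean(weight)

  records <- data.frame(
    woman_id = seq_len(n), region = region, residence = residence,
    wealth_quintile = as.character(wealth), education = education,
    anc4 = anc4, weight = weight, stratum_id = stratum_id,
    cluster_id = cluster_id, stringsAsFactors = FALSE)
  records$outcome <- records$anc4
  list(records = records, truth = truth)
}

#' Write synthetic survey records / truth table to CSV
#'
#' `write_survey_csv()` writes the unit-level schema (`woman_id, region,
#' residence, wealth_quintile, education, anc4, weight, stratum_id,
#' cluster_id`); `write_truth_csv()` writes `dimension, subgroup,
#' true_coverage`.
#'
#' @param records,truth objects from [generate_survey()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_survey_csv <- function(records, path) {
  cols <- c("woman_id", "region", "residence", "wealth_quintile",
            "education", "anc4", "weight", "stratum_id", "cluster_id")
  write.csv(records[, cols], path, row.names = FALSE, quote = TRUE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_survey_csv
#' @export
write_truth_csv <- function(truth, path) {
  write.csv(truth$subgroups, path, row.names = FALSE, quote = TRUE,
            fileEncoding = "UTF-8")
  invisible(path)
}
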