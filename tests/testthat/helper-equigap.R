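# Shared fixtures built in code.

# Compact two-region design for fast simulation tests.
small_config <- function(seed = 1, n_clusters_per_stratum = 4L,
                         n_women_per_cluster = 25L, ...) {
  synthetic_config(
    regions = c("North", "South"),
    region_share = c(North = 0.5, South = 0.5),
    urban_share_by_region = c(North = 0.6, South = 0.4),
    region_effects = c(North = 0.2, South = -0.2),
    n_clusters_per_stratum = n_clusters_per_stratum,
    n_women_per_cluster = n_women_per_cluster,
    seed = seed, ...)
}

# Two-region proportionate (self-weighting) design: equal region shares and
# urban fractions, so base weights are constant and subgroup sampling error
# is at the binomial floor. Used where estimates from a single survey are
# compared to truth at a fixed percentage-point scale.
proportionate_config <- function(seed = 1, n_clusters_per_stratum = 50L,
                                 n_women_per_cluster = 100L, ...) {
  synthetic_config(
    regions = c("North", "South"),
    region_share = c(North = 0.5, South = 0.5),
    urban_share_by_region = c(North = 0.5, South = 0.5),
    region_effects = c(North = 0.2, South = -0.2),
    n_clusters_per_stratum = n_clusters_per_stratum,
    n_women_per_cluster = n_women_per_cluster,
    cluster_sd = 0, weight_dispersion = 0,
    seed = seed, ...)
}

# Flat design: all effects zero, coverage 50% everywhere.
null_config <- function(seed = 1, n_clusters = 14L, n_women = 40L,
                        cluster_sd = 0.3) {
  synthetic_config(
    intercept = qlogis(0.5),
    wealth_effects = rep(0, 5), education_effects = rep(0, 3),
    urban_effect = 0,
    region_effects = setNames(rep(0, 18), angola_regions()),
    n_clusters_per_stratum = n_clusters, n_women_per_cluster = n_women,
    cluster_sd = cluster_sd, seed = seed)
}

# Brute-force per-record weighted prevalence: the independent oracle for the
# grouped implementation. Walks the records one by one, collecting each
# subgroup's members in encounter order, then sums.
brute_prevalence <- function(records, column) {
  members <- list()
  for (i in seq_len(nrow(records))) {
    g <- as.character(records[[column]][i])
    members[[g]] <- c(members[[g]], i)
  }
  data.frame(subgroup = names(members),
             estimate = vapply(members, function(idx)
               100 * (sum(records$weight[idx] * records$outcome[idx]) /
                        sum(records$weight[idx])), numeric(1)),
             n = lengths(members),
             stringsAsFactors = FALSE, row.names = NULL)
}

# Random tiny survey (single stratum structure irrelevant for point
# estimates) for oracle-equivalence checks.
random_instance <- function(n, n_groups = 3L) {
  data.frame(
    outcome = sample(0:1, n, replace = TRUE),
    weight = runif(n, 0.1, 3),
    stratum_id = sample(c("s1", "s2"), n, replace = TRUE),
    cluster_id = as.character(sample(1:6, n, replace = TRUE)),
    grp = sample(paste0("g", seq_len(n_groups)), n, replace = TRUE),
    stringsAsFactors = FALSE)
}

grp_dimension <- function(labels = paste0("g", 1:3)) {
  dimension_spec("grp", labels, "non_ordered")
}

published_fixture <- function() angola_anc4_2015()
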