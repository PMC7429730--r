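test_that("weighted prevalence matches hand computation and unweighted identity", {
  rec <- data.frame(outcome = c(1, 0, 1), weight = c(2, 1, 1),
                    stratum_id = "s", cluster_id = c("a", "a", "b"),
                    grp = "g1", stringsAsFactors = FALSE)
  est <- suppressWarnings(
    weighted_prevalence(rec, grp_dimension(c("g1", "g2")),
                        suppress_below = 0))
  expect_equal(est$estimate, 75)
  expect_equal(est$population, 3)

  set.seed(4)
  rec2 <- random_instance(200)
  rec2$weight <- rep(1, 200)
  est2 <- suppressWarnings(weighted_prevalence(rec2, grp_dimension()))
  for (g in est2$subgroup) {
    idx <- rec2$grp == g
    expect_equal(est2$estimate[est2$subgroup == g],
                 100 * mean(rec2$outcome[idx]))
  }
})

test_that("grouped implementation equals the brute-force per-record oracle", {
  set.seed(10)
  for (i in 1:30) {
    rec <- random_instance(sample(20:200, 1))
    est <- suppressWarnings(weighted_prevalence(rec, grp_dimension(),
                                                suppress_below = 0))
    oracle <- brute_prevalence(rec, "grp")
    m <- match(est$subgroup, oracle$subgroup)
    expect_identical(est$estimate, oracle$estimate[m])
    expect_equal(est$population, oracle$n[m], ignore_attr = TRUE)
  }
})

test_that("share-weighted subgroup estimates aggregate exactly to the national average", {
  sim <- generate_survey(small_config(seed = 21))
  nat <- national_average(sim$records, population = "weighted")
  dims <- synthetic_dimensions()
  dims$region <- dimension_spec("region", c("North", "South"), "non_ordered")
  for (d in c("wealth_quintile", "education", "residence", "region")) {
    est <- weighted_prevalence(sim$records, dims[[d]],
                               population = "weighted", suppress_below = 0)
    shares <- est$population / sum(est$population)
    expect_equal(sum(shares * est$estimate), nat$estimate,
                 tolerance = 1e-9)
  }
})

test_that("subgroup and national estimates track the generator truth at n ~ 20,000", {
  # proportionate design: subgroup sampling error is at the binomial floor,
  # so 1.5 pp is a 2-3 sigma band for every subgroup
  cfg <- proportionate_config(seed = 31)
  sim <- generate_survey(cfg)
  expect_gt(nrow(sim$records), 19000)
  nat <- national_average(sim$records)
  expect_lt(abs(nat$estimate - sim$truth$national_average), 1)
  for (d in c("wealth_quintile", "education", "residence")) {
    est <- weighted_prevalence(sim$records, synthetic_dimensions()[[d]])
    truth <- truth_summary(sim$truth, d)
    err <- abs(est$estimate -
               truth$true_coverage[match(est$subgroup, truth$subgroup)])
    expect_true(all(err < 1.5))
  }
})

test_that("logit-scale intervals reproduce closed-form arithmetic", {
  ci <- estimate_interval(50, 5)
  expect_equal(as.numeric(ci), c(40.32, 59.68), tolerance = 5e-3)
  expect_identical(attr(ci, "method"), "logit_wald")
  # asymmetry: upper gap shorter than lower gap for p > 50
  ci2 <- estimate_interval(88, 2)
  expect_lt(ci2[2] - 88, 88 - ci2[1])
  # degenerate
  ci3 <- estimate_interval(42, 0)
  expect_identical(as.numeric(ci3), c(42, 42))
  # boundary falls back to an exact interval when n is known
  ci4 <- estimate_interval(0, 1, n_eff = 50)
  expect_identical(attr(ci4, "method"), "clopper_pearson")
  expect_equal(ci4[[1]], 0)
  expect_gt(ci4[[2]], 0)
})

test_that("published-summary ingestion back-derives standard errors", {
  rows <- data.frame(
    dimension = "economic_status",
    subgroup = c("Quintile 1 (poorest)", "Quintile 5 (richest)"),
    estimate = c(34.03, 88.18), ci_lower = c(30.44, 85.23),
    ci_upper = c(37.82, 90.61), population = c(1674, 1422),
    stringsAsFactors = FALSE)
  out <- summaries_from_published(rows)
  expect_equal(out$se, c(1.883, 1.372), tolerance = 1e-3)
  expect_identical(out$ci_lower, rows$ci_lower)  # bounds kept verbatim

  # symmetric interval round-trips the SE exactly
  s <- 2.345
  sym <- data.frame(dimension = "d", subgroup = "g", estimate = 50,
                    ci_lower = 50 - 1.96 * s, ci_upper = 50 + 1.96 * s,
                    population = 100)
  expect_equal(summaries_from_published(sym)$se, s, tolerance = 1e-12)

  bad <- rows
  bad$ci_lower[2] <- 89
  expect_error(summaries_from_published(bad), "Quintile 5")
})

test_that("ignoring clustering understates the variance when clusters matter", {
  cfg <- small_config(seed = 8, cluster_sd = 0.8,
                      n_clusters_per_stratum = 10L,
                      n_women_per_cluster = 50L)
  r <- generate_survey(cfg)$records
  lin <- equigap:::svy_domain_mean(r$outcome, r$weight, r$stratum_id,
                                   r$cluster_id)
  iid <- equigap:::svy_iid_se(r$outcome, r$weight)
  expect_gt(lin$se, iid)
})

test_that("standard errors shrink as the sample grows", {
  sizes <- c(4L, 8L, 16L)
  se_by_size <- sapply(sizes, function(ncl) {
    mean(sapply(1:10, function(s) {
      r <- generate_survey(small_config(seed = s,
                                        n_clusters_per_stratum = ncl))$records
      national_average(r)$se
    }))
  })
  expect_true(all(diff(se_by_size) < 0))
})

test_that("small subgroups are flagged suppressed, not dropped", {
  rec <- data.frame(outcome = rep(0:1, 30), weight = 1,
                    stratum_id = "s",
                    cluster_id = rep(c("a", "b", "c"), each = 20),
                    grp = c(rep("big", 50), rep("small", 10)),
                    stringsAsFactors = FALSE)
  est <- weighted_prevalence(rec, grp_dimension(c("big", "small")))
  expect_identical(est$suppressed, c(FALSE, TRUE))
  expect_equal(nrow(est), 2L)
})

test_that("malformed record frames fail with informative errors", {
  rec <- data.frame(outcome = c(0, 2), weight = 1, stratum_id = "s",
                    cluster_id = c("a", "b"))
  expect_error(national_average(rec), "non-binary outcome at row")
  rec2 <- data.frame(outcome = c(0, 1), weight = c(1, -1), stratum_id = "s",
                     cluster_id = c("a", "b"))
  expect_error(national_average(rec2), "non-positive weight")
  expect_error(national_average(data.frame(outcome = 1, weight = 1)),
               "missing column")
})
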