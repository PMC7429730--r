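# One-row helpers for constructing subgroup inputs by hand.
sg <- function(dimension, subgroup, estimate, se = 1, population = 100) {
  data.frame(dimension = dimension, subgroup = subgroup, estimate = estimate,
             se = se, ci_lower = estimate - 1.96 * se,
             ci_upper = estimate + 1.96 * se, population = population,
             suppressed = FALSE, stringsAsFactors = FALSE)
}
nat <- function(estimate, se = 0.5, population = 1000) {
  structure(list(estimate = estimate, se = se, ci_lower = NA, ci_upper = NA,
                 population = population), class = "national_average")
}

test_that("contrast selection follows dimension semantics", {
  tab <- published_fixture()
  dims <- angola_dimensions()
  econ <- tab$subgroups[tab$subgroups$dimension == "economic_status", ]
  ct <- select_contrast(econ, dims$economic_status)
  expect_identical(ct$reference, "Quintile 5 (richest)")
  expect_identical(ct$comparison, "Quintile 1 (poorest)")

  edu <- tab$subgroups[tab$subgroups$dimension == "education", ]
  ct <- select_contrast(edu, dims$education)
  expect_identical(ct$reference, "Secondary school +")
  expect_identical(ct$comparison, "No education")  # primary skipped

  reg <- tab$subgroups[tab$subgroups$dimension == "region", ]
  ct <- select_contrast(reg, dims$region)
  expect_identical(ct$reference, "Luanda")
  expect_identical(ct$comparison, "Cuanza Sul")
  expect_false(ct$tie)

  # ties in a non-ordered dimension break by category-list order, flagged
  tied <- rbind(sg("d", "a", 50), sg("d", "b", 50))
  ct <- select_contrast(tied, dimension_spec("d", c("b", "a"), "non_ordered"))
  expect_identical(ct$reference, "b")
  expect_true(ct$tie)
})

test_that("published contrasts reproduce the published measure estimates", {
  tab <- published_fixture()
  s <- tab$subgroups
  rich <- s[s$subgroup == "Quintile 5 (richest)", ]
  poor <- s[s$subgroup == "Quintile 1 (poorest)", ]
  urban <- s[s$subgroup == "Urban", ]
  rural <- s[s$subgroup == "Rural", ]
  sec <- s[s$subgroup == "Secondary school +", ]
  luanda <- s[s$subgroup == "Luanda", ]
  mu <- tab$national

  expect_equal(ineq_difference(rich, poor)$estimate, 54.15)
  expect_equal(ineq_difference(urban, rural)$estimate, 34.35)
  expect_equal(ineq_ratio(rich, poor)$estimate, 2.59, tolerance = 2e-3)
  expect_equal(ineq_ratio(urban, rural)$estimate, 1.87, tolerance = 2e-3)

  mu$se <- 0.5
  expect_equal(ineq_par(sec, mu, 2995 / 8492)$estimate, 19.89,
               tolerance = 5e-3)
  par_lu <- ineq_par(luanda, mu, 2696 / 8492)
  expect_equal(par_lu$estimate, 21.78, tolerance = 5e-3)
  paf <- ineq_paf(ineq_par(sec, mu, 2995 / 8492), mu)
  expect_equal(paf$estimate, 32.38, tolerance = 5e-3)
})

test_that("equal subgroups collapse every measure to its null value", {
  a <- sg("d", "a", 63.2, se = 1.1, population = 400)
  b <- sg("d", "b", 63.2, se = 0.9, population = 600)
  mu <- nat(63.2, se = 0.7)
  expect_identical(ineq_difference(a, b)$estimate, 0)
  expect_identical(ineq_ratio(a, b)$estimate, 1)
  pr <- ineq_par(a, mu, 0.4)
  expect_identical(pr$estimate, 0)
  expect_identical(ineq_paf(pr, mu)$estimate, 0)
})

test_that("PAF is PAR rescaled by 100/mu, bounds included, exactly", {
  tab <- published_fixture()
  fit <- equigap_published(tab$subgroups, tab$national)
  m <- fit$measures
  f <- 100 / tab$national$estimate
  for (d in unique(m$dimension)) {
    pr <- m[m$dimension == d & m$measure == "PAR", ]
    pf <- m[m$dimension == d & m$measure == "PAF", ]
    expect_identical(pf$estimate, f * pr$estimate)
    expect_identical(pf$ui_lower, f * pr$ui_lower)
    expect_identical(pf$ui_upper, f * pr$ui_upper)
  }
})

test_that("raising the reference estimate weakly increases all four measures", {
  mu0 <- nat(60)
  comp <- sg("d", "lo", 40, population = 500)
  prev <- c(D = -Inf, R = -Inf, PAR = -Inf, PAF = -Inf)
  for (ref_est in c(55, 65, 75, 85)) {
    ref <- sg("d", "hi", ref_est, population = 500)
    cur <- c(D = ineq_difference(ref, comp)$estimate,
             R = ineq_ratio(ref, comp)$estimate,
             PAR = ineq_par(ref, mu0, 0.5)$estimate,
             PAF = ineq_paf(ineq_par(ref, mu0, 0.5), mu0)$estimate)
    expect_true(all(cur >= prev))
    prev <- cur
  }
})

test_that("measures agree with brute-force recomputation on random inputs", {
  set.seed(77)
  for (i in 1:50) {
    e <- runif(2, 5, 95)
    s <- runif(2, 0.2, 3)
    pops <- sample(100:2000, 2)
    mu_est <- runif(1, min(e), max(e))
    mu_se <- runif(1, 0.1, 1)
    ref <- sg("d", "ref", max(e), se = s[1], population = pops[1])
    comp <- sg("d", "comp", min(e), se = s[2], population = pops[2])
    mu <- nat(mu_est, se = mu_se, population = sum(pops))
    share <- runif(1, 0.05, 0.5)

    d <- ineq_difference(ref, comp)
    expect_equal(d$estimate, max(e) - min(e))
    expect_equal(d$ui_lower, (max(e) - min(e)) -
                   1.96 * sqrt(s[1]^2 + s[2]^2))
    expect_true(d$estimate >= -100 && d$estimate <= 100)

    r <- ineq_ratio(ref, comp)
    expect_equal(r$estimate, max(e) / min(e))
    expect_gt(r$ui_lower, 0)
    sl <- sqrt((s[1] / max(e))^2 + (s[2] / min(e))^2)
    expect_equal(r$ui_upper, max(e) / min(e) * exp(1.96 * sl))

    pr <- ineq_par(ref, mu, share)
    expect_equal(pr$estimate, max(e) - mu_est)
    v <- s[1]^2 + mu_se^2 - 2 * share * s[1]^2
    expect_equal(pr$ui_upper - pr$ui_lower, 2 * 1.96 * sqrt(v))

    pf <- ineq_paf(pr, mu)
    expect_equal(pf$estimate, 100 * pr$estimate / mu_est)
  }
})

test_that("degenerate and invalid inputs are handled explicitly", {
  ref <- sg("d", "a", 70, se = 0)
  comp <- sg("d", "b", 30, se = 0)
  d <- ineq_difference(ref, comp)
  expect_identical(c(d$ui_lower, d$ui_upper), c(40, 40))

  zero <- sg("d", "b", 0)
  expect_error(ineq_ratio(ref, zero), "ratio undefined")

  nose <- sg("d", "b", 30)
  nose$se <- NA_real_
  expect_error(ineq_difference(ref, nose), "missing standard error.*'b'")

  # reference below mu: PAR truncated to 0 and flagged, UI still spans 0
  low_ref <- sg("d", "a", 55, se = 1)
  pr <- ineq_par(low_ref, nat(60), 0.3)
  expect_identical(pr$estimate, 0)
  expect_identical(pr$flag, "truncated")
  expect_true(pr$ui_lower <= 0 && pr$ui_upper >= 0)
  expect_identical(ineq_paf(pr, nat(60))$estimate, 0)

  expect_error(ineq_paf(pr, nat(0)), "positive")
})

test_that("significance follows the UI-excludes-null rule", {
  expect_true(is_significant(data.frame(measure = "D", ui_lower = 49.59,
                                        ui_upper = 58.70)))
  expect_false(is_significant(data.frame(measure = "R", ui_lower = 0.9,
                                         ui_upper = 1.2)))
  expect_false(is_significant(data.frame(measure = "PAR", ui_lower = -0.5,
                                         ui_upper = 2.0)))
  expect_true(is_significant(data.frame(measure = "R", ui_lower = 1.05,
                                        ui_upper = 1.4)))
  # the significant column of computed measures obeys the same rule
  tab <- published_fixture()
  fit <- equigap_published(tab$subgroups, tab$national)
  m <- fit$measures
  null_v <- ifelse(m$measure == "R", 1, 0)
  expect_identical(m$significant, m$ui_lower > null_v | m$ui_upper < null_v)
})
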