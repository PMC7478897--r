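test_that("scenario validation names the offending field", {
  expect_error(mdd_scenario(n_clusters = 0), "n_clusters")
  expect_error(mdd_scenario(n_clusters = 5, n_strata = 3), "n_clusters")
  expect_error(mdd_scenario(weight_dispersion = -1), "weight_dispersion")
  expect_error(mdd_scenario(group_logit_intercepts = rep(-1, 6)),
               "group_logit_intercepts")
  expect_error(mdd_scenario(age_distribution = rep(0, 18)),
               "age_distribution")
})

test_that("forced probabilities and seeded determinism behave exactly", {
  sc <- small_scenario(bf_logit_intercept = Inf)
  co <- generate_cohort(sc, seed = 4)
  expect_true(all(co$breastfed == 1L))

  sc2 <- small_scenario()
  a <- generate_cohort(sc2, seed = 99)
  b <- generate_cohort(sc2, seed = 99)
  expect_identical(a, b)
  expect_false(identical(a, generate_cohort(sc2, seed = 100)))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123)
  r1 <- runif(3)
  set.seed(123)
  invisible(generate_cohort(small_scenario(), seed = 7))
  r2 <- runif(3)
  expect_identical(r1, r2)
})

test_that("weights have mean 1 and the configured dispersion", {
  sc0 <- small_scenario(weight_dispersion = 0)
  expect_true(all(generate_cohort(sc0, seed = 1)$weight == 1))

  sc <- mdd_scenario(n_clusters = 100, children_per_cluster = 100,
                     n_strata = 2, weight_dispersion = 0.4)
  w <- generate_cohort(sc, seed = 2)$weight
  expect_true(all(w > 0))
  expect_lt(abs(mean(w) - 1), 3 * 0.4 / sqrt(length(w)))
  expect_lt(abs(sd(w) / mean(w) - 0.4), 0.02)
})

test_that("empirical frequencies converge to the scenario's logistic curves", {
  sc <- mdd_scenario(n_clusters = 500, children_per_cluster = 100,
                     n_strata = 5, bf_logit_intercept = 3.0,
                     bf_logit_slope = -0.15,
                     group_logit_intercepts = c(1, -0.5, -1, -1.5, -2, 0, -0.8),
                     group_logit_slope = 0.07, child_heterogeneity_sd = 0)
  co <- generate_cohort(sc, seed = 31)
  expect_gt(nrow(co), 45000)

  # independent direct evaluation of the logistic formula at month 12
  p12 <- 1 / (1 + exp(-(3.0 - 0.15 * 12)))
  sub <- co[co$age_months == 12, ]
  se_bin <- sqrt(p12 * (1 - p12) / nrow(sub))
  expect_lt(abs(mean(sub$breastfed) - p12), 3 * se_bin)

  pg12 <- 1 / (1 + exp(-(-0.5 + 0.07 * 12)))
  se_g <- sqrt(pg12 * (1 - pg12) / nrow(sub))
  expect_lt(abs(mean(sub$legumes) - pg12), 3 * se_g)
})

test_that("declining breastfeeding slope orders the age bands", {
  sc <- mdd_scenario(n_clusters = 100, children_per_cluster = 50,
                     n_strata = 4, bf_logit_slope = -0.1)
  co <- generate_cohort(sc, seed = 5)
  young <- co$age_months <= 11
  expect_gt(mean(co$breastfed[young]), mean(co$breastfed[!young]))
})

test_that("degenerate scenarios give the forced indicator truths", {
  all_on <- small_scenario(group_logit_intercepts = rep(Inf, 7),
                           child_heterogeneity_sd = 0)
  tv <- true_indicator_values(all_on)
  expect_equal(tv$mdd7_true, 1)
  expect_equal(tv$mean7_true, 7)

  only_bm <- small_scenario(group_logit_intercepts = rep(-Inf, 7),
                            bf_logit_intercept = Inf,
                            child_heterogeneity_sd = 0)
  tv2 <- true_indicator_values(only_bm)
  expect_equal(tv2$mdd8_true, 0)
  expect_equal(tv2$mean8_true, 1)
  expect_equal(tv2$bf_6_11_true, 1)
})

test_that("exact enumeration agrees with Monte Carlo on the same scenario", {
  sc <- small_scenario(child_heterogeneity_sd = 0,
                       group_logit_intercepts = c(0.5, -1, -1.5, -2, -2.5, -0.5, -1),
                       bf_logit_intercept = 3, bf_logit_slope = -0.12)
  ex <- true_indicator_values(sc, method = "exact")
  n_mc <- 1e6
  mc <- true_indicator_values(sc, n_mc = n_mc, seed = 17,
                              method = "monte-carlo")
  expect_identical(ex$method, "exact")
  expect_identical(mc$method, "monte-carlo")
  for (q in c("mdd7_true", "mdd8_true")) {
    se_mc <- sqrt(ex[[q]] * (1 - ex[[q]]) / n_mc)
    expect_lt(abs(ex[[q]] - mc[[q]]), 3 * se_mc)
  }
  # mean scores: bound the MC error by the maximal score variance
  expect_lt(abs(ex$mean7_true - mc$mean7_true), 3 * sqrt(7^2 / 4 / n_mc))
  expect_error(true_indicator_values(small_scenario(), method = "exact"),
               "heterogeneity")
})

test_that("presets hit their documented calibration targets", {
  ps <- preset_scenarios()
  expect_setequal(names(ps),
                  c("high-bf-low-diversity", "low-bf-high-diversity"))

  tv_eth <- true_indicator_values(ps[["high-bf-low-diversity"]],
                                  n_mc = 4e5, seed = 8)
  expect_lt(abs(tv_eth$bf_12_23_true - 0.793), 0.05)
  expect_lt(abs(tv_eth$mean7_true - 1.8), 0.2)

  tv_sa <- true_indicator_values(ps[["low-bf-high-diversity"]],
                                 n_mc = 4e5, seed = 8)
  expect_lt(abs(tv_sa$mean7_true - 3.5), 0.2)
  expect_lt(abs(tv_sa$bf_12_23_true - 0.347), 0.05)

  for (p in ps) {
    p$n_clusters <- 50
    expect_no_error(generate_cohort(p, seed = 3))
  }
})

test_that("scenario files round-trip through the reader", {
  sc <- read_scenario(extdata("scenario_example.yaml"))
  expect_s3_class(sc, "mdd_scenario")
  expect_identical(sc$label, "example")
  expect_length(sc$group_logit_intercepts, 7)

  bad <- tempfile(fileext = ".yaml")
  writeLines("n_clusters: 10\nnot_a_field: 3", bad)
  expect_error(read_scenario(bad), "not_a_field")
})
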