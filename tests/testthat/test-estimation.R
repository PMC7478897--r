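test_that("unweighted special cases reduce to the obvious answers", {
  e <- weighted_proportion(c(1, 0, 1, 0), rep(1, 4))
  expect_equal(e$estimate, 0.5)
  expect_identical(e$n, 4L)
  expect_identical(e$n_psu, 4L)

  const <- weighted_proportion(rep(1, 6), rep(1, 6))
  expect_equal(const$estimate, 1)
  expect_equal(const$se, 0)
  expect_equal(c(const$ci_low, const$ci_high), c(1, 1))
})

test_that("equal-weight independent-PSU SE equals the SRS closed form", {
  set.seed(10)
  y <- rbinom(40, 1, 0.3)
  p <- mean(y)
  e <- weighted_proportion(y, rep(2.5, 40))
  expect_equal(e$se, sqrt(p * (1 - p) / (40 - 1)), tolerance = 1e-12)
})

test_that("Taylor SE matches the brute-force linearization on the packaged fixture", {
  rec <- read_child_records(extdata("design_fixture.csv"))
  expect_identical(nrow(rec), 30L)
  expect_identical(length(unique(rec$cluster_id)), 6L)
  expect_identical(length(unique(rec$stratum_id)), 3L)
  scores <- score_cohort(rec)

  for (y in list(rec$breastfed, as.numeric(scores$mdd7))) {
    e <- weighted_proportion(y, rec$weight, rec$cluster_id, rec$stratum_id)
    expect_equal(e$estimate, sum(rec$weight * y) / sum(rec$weight),
                 tolerance = 1e-12)
    expect_equal(e$se,
                 brute_taylor_se(y, rec$weight, rec$cluster_id, rec$stratum_id),
                 tolerance = 1e-10)
  }
  m <- weighted_mean(scores$score7, rec$weight, rec$cluster_id, rec$stratum_id)
  expect_equal(m$se,
               brute_taylor_se(scores$score7, rec$weight, rec$cluster_id,
                               rec$stratum_id),
               tolerance = 1e-10)
})

test_that("Taylor SE tracks a delete-one-cluster jackknife on a well-behaved design", {
  sc <- mdd_scenario(n_clusters = 40, children_per_cluster = 15, n_strata = 4)
  co <- generate_cohort(sc, seed = 14)
  y <- co$breastfed
  e <- weighted_proportion(y, co$weight, co$cluster_id, co$stratum_id)
  jk <- jackknife_se(y, co$weight, co$cluster_id, co$stratum_id)
  expect_lt(abs(e$se - jk) / jk, 0.15)
})

test_that("estimates, SEs and CIs are invariant to the weight scale", {
  rec <- read_child_records(extdata("design_fixture.csv"))
  a <- weighted_proportion(rec$breastfed, rec$weight,
                           rec$cluster_id, rec$stratum_id)
  b <- weighted_proportion(rec$breastfed, rec$weight * 1e6,
                           rec$cluster_id, rec$stratum_id)
  expect_equal(a[c("estimate", "se", "ci_low", "ci_high")],
               b[c("estimate", "se", "ci_low", "ci_high")], tolerance = 1e-12)
})

test_that("two-cluster weighted mean matches the hand-worked formula", {
  m <- weighted_mean(c(2, 4), c(1, 1), clusters = c("a", "b"))
  expect_equal(m$estimate, 3)
  # z totals are +-0.5; one stratum, 2 PSUs: V = 2 * (0.25 + 0.25) = 1
  expect_equal(m$se, 1, tolerance = 1e-12)
  expect_equal(m$ci_low, 3 - 1.959964, tolerance = 1e-10)
  const <- weighted_mean(rep(3, 5), rep(1, 5))
  expect_equal(const$se, 0)
})

test_that("score accounting propagates exactly through weighted estimation", {
  co <- generate_cohort(small_scenario(), seed = 41)
  s <- score_cohort(co)
  m7 <- weighted_mean(s$score7, co$weight, co$cluster_id, co$stratum_id)
  m8 <- weighted_mean(s$score8, co$weight, co$cluster_id, co$stratum_id)
  pbf <- weighted_proportion(co$breastfed, co$weight, co$cluster_id,
                             co$stratum_id)
  expect_equal(m8$estimate - m7$estimate, pbf$estimate, tolerance = 1e-10)
})

test_that("logit intervals respect [0,1] and bracket the estimate", {
  set.seed(6)
  for (p_true in c(0.05, 0.5, 0.9)) {
    y <- rbinom(200, 1, p_true)
    w <- rgamma(200, 4, 4)
    cl <- rep(1:20, each = 10)
    e <- weighted_proportion(y, w, cl)
    expect_gte(e$ci_low, 0)
    expect_lte(e$ci_high, 1)
    expect_true(e$ci_low <= e$estimate && e$estimate <= e$ci_high)
    wd <- weighted_proportion(y, w, cl, method = "wald")
    expect_true(wd$ci_low <= wd$estimate && wd$estimate <= wd$ci_high)
    expect_identical(wd$method, "wald")
  }
})

test_that("singleton-PSU strata fail loudly unless centering is requested", {
  y <- c(1, 0, 1, 0, 1)
  st <- c("a", "a", "a", "a", "b")
  cl <- c(1, 1, 2, 2, 3)
  expect_error(weighted_proportion(y, rep(1, 5), cl, st), "single PSU")
  e <- weighted_proportion(y, rep(1, 5), cl, st, singleton = "centered")
  expect_true(is.finite(e$se) && e$se > 0)
})

test_that("age-band domain estimation keeps the design and flags empty bands", {
  rec <- records_with_scores(rep(3, 8), breastfed = c(rep(1, 4), rep(0, 4)),
                             cluster = rep(1:4, each = 2),
                             age = c(6L, 8L, 9L, 11L, 12L, 15L, 19L, 23L))
  bands <- estimate_by_ageband(rec)
  expect_equal(bands[["6-11"]]$estimate, 1)
  expect_equal(bands[["12-23"]]$estimate, 0)

  # domain point estimate equals the naive subset ratio
  co <- generate_cohort(small_scenario(), seed = 9)
  b <- estimate_by_ageband(co)
  young <- co[co$age_months <= 11, ]
  naive <- sum(young$weight * young$breastfed) / sum(young$weight)
  expect_equal(b[["6-11"]]$estimate, naive, tolerance = 1e-12)
  # full PSU count is retained under domain estimation
  expect_identical(b[["6-11"]]$n_psu, length(unique(co$cluster_id)))
  expect_identical(b[["6-11"]]$n, sum(co$age_months <= 11))

  only_young <- co[co$age_months <= 11, ]
  eb <- estimate_by_ageband(only_young)
  expect_identical(eb[["12-23"]]$n, 0L)
  expect_true(is.na(eb[["12-23"]]$estimate))

  expect_error(estimate_by_ageband(co, bands = list(a = c(6, 10))),
               "partition")
})

test_that("interval overlap uses the closed-interval convention", {
  expect_false(ci_overlap(c(43.4, 51.2), c(35.0, 42.1)))
  expect_true(ci_overlap(c(10, 20), c(10, 20)))
  expect_true(ci_overlap(c(10, 20), c(20, 30)))
  p <- weighted_proportion(c(1, 0, 1), rep(1, 3))
  m <- weighted_mean(c(1, 0, 1), rep(1, 3))
  expect_error(ci_overlap(p, m), "scale")
})

test_that("nominal CI coverage holds across repeated sampling", {
  sc <- mdd_scenario(n_clusters = 30, children_per_cluster = 20,
                     n_strata = 3, child_heterogeneity_sd = 0)
  truth <- true_indicator_values(sc)$mdd7_true
  hits <- 0L
  n_rep <- 120L
  for (r in seq_len(n_rep)) {
    co <- generate_cohort(sc, seed = 5000 + r)
    s <- score_cohort(co)
    e <- weighted_proportion(s$mdd7, co$weight, co$cluster_id, co$stratum_id)
    if (e$ci_low <= truth && truth <= e$ci_high) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.88)
  expect_lte(hits / n_rep, 0.99)
})
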