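expit <- function(x) stats::plogis(x)

group_names <- function() {
  c("grains", "legumes", "dairy", "flesh", "eggs",
    "vita_fruit_veg", "other_fruit_veg")
}

cohort_columns <- function() {
  c("child_id", "cluster_id", "stratum_id", "weight", "age_months",
    "breastfed", group_names(), "country_label")
}

# Run code under a given seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

bf_prob <- function(sc, age) expit(sc$bf_logit_intercept + sc$bf_logit_slope * age)

# 18 x 7 matrix of P(group g | age, u = shift)
group_prob <- function(sc, ages, shift = 0) {
  outer(sc$group_logit_slope * ages + shift, sc$group_logit_intercepts, "+") |>
    expit()
}

#' Generate a synthetic child-level survey cohort
#'
#' Draws a stratified cluster sample of children aged 6-23 months from the
#' feeding model described in [mdd_scenario()].  Clusters are assigned to
#' strata round-robin, cluster sizes are Poisson around
#' `children_per_cluster` (minimum 1), sampling weights are gamma with mean
#' 1 and coefficient of variation `weight_dispersion` (exactly 1 when the
#' dispersion is 0), and each child's seven food-group indicators share one
#' latent normal diet propensity.  Identical `(scenario, seed)` pairs yield
#' identical cohorts; the caller's RNG state is left untouched.
#'
#' @param scenario an [mdd_scenario()].
#' @param seed integer seed controlling all randomness.
#' @return A `data.frame`, one row per child, with columns `child_id`,
#'   `cluster_id`, `stratum_id`, `weight`, `age_months`, `breastfed`, the
#'   seven food-group indicators (`grains`, `legumes`, `dairy`, `flesh`,
#'   `eggs`, `vita_fruit_veg`, `other_fruit_veg`) and `country_label`.
#' @export
#' @examples
#' sc <- preset_scenarios()[["high-bf-low-diversity"]]
#' head(generate_cohort(sc, seed = 1))
generate_cohort <- function(scenario, seed) {
  validate_scenario(scenario)
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop("a single integer 'seed' is required", call. = FALSE)
  sc <- scenario
  with_seed(seed, {
    n_cl <- sc$n_clusters
    stratum <- rep_len(seq_len(sc$n_strata), n_cl)
    sizes <- pmax(1L, stats::rpois(n_cl, sc$children_per_cluster))
    n <- sum(sizes)
    cl_idx <- rep.int(seq_len(n_cl), sizes)

    w <- if (sc$weight_dispersion == 0) rep(1, n) else {
      shape <- 1 / sc$weight_dispersion^2
      stats::rgamma(n, shape = shape, rate = shape)
    }

    p_age <- sc$age_distribution / sum(sc$age_distribution)
    age <- sample(6:23, n, replace = TRUE, prob = p_age)
    bfed <- as.integer(stats::runif(n) < bf_prob(sc, age))

    u <- if (sc$child_heterogeneity_sd > 0)
      stats::rnorm(n, 0, sc$child_heterogeneity_sd) else numeric(n)
    eta <- outer(sc$group_logit_slope * age + u,
                 sc$group_logit_intercepts, "+")
    groups <- matrix(as.integer(stats::runif(7L * n) < expit(eta)), nrow = n)
    colnames(groups) <- group_names()

    out <- data.frame(
      child_id = sprintf("c%06d", seq_len(n)),
      cluster_id = sprintf("cl%04d", cl_idx),
      stratum_id = sprintf("s%03d", stratum[cl_idx]),
      weight = w,
      age_months = as.integer(age),
      breastfed = bfed,
      groups,
      country_label = sc$label,
      stringsAsFactors = FALSE)
    out
  })
}

#' Population indicator values implied by a scenario
#'
#' Evaluates the true (population) values of the quantities the package
#' estimates from samples: MDD-7 and MDD-8 prevalence, breastfeeding
#' prevalence in the 6-11 and 12-23 month age bands, and the mean 7- and
#' 8-group diversity scores.  When `child_heterogeneity_sd` is 0 the seven
#' group indicators are conditionally independent given age and the values
#' are computed by exact summation over the score distribution at each age
#' (no Monte Carlo error).  Otherwise the latent propensity is integrated
#' out by Monte Carlo over `n_mc` simulated children.
#'
#' @param scenario an [mdd_scenario()].
#' @param n_mc Monte-Carlo sample size when heterogeneity is positive
#'   (at least 1e5 recommended).
#' @param seed seed for the Monte-Carlo path.
#' @param method `"auto"` (exact when heterogeneity is 0, else
#'   Monte-Carlo), or force `"exact"` / `"monte-carlo"`.
#' @return Named list: `mdd7_true`, `mdd8_true`, `bf_6_11_true`,
#'   `bf_12_23_true`, `mean7_true`, `mean8_true`, and `method`
#'   (`"exact"` or `"monte-carlo"`).
#' @export
#' @examples
#' sc <- mdd_scenario(child_heterogeneity_sd = 0)
#' true_indicator_values(sc)$method
true_indicator_values <- function(scenario, n_mc = 1e5, seed = 1,
                                  method = c("auto", "exact", "monte-carlo")) {
  validate_scenario(scenario)
  method <- match.arg(method)
  sc <- scenario
  ages <- 6:23
  pi_a <- sc$age_distribution / sum(sc$age_distribution)
  p_bf <- bf_prob(sc, ages)

  if (method == "exact" && sc$child_heterogeneity_sd > 0)
    stop("exact enumeration requires child_heterogeneity_sd = 0",
         call. = FALSE)
  use_exact <- method == "exact" ||
    (method == "auto" && sc$child_heterogeneity_sd == 0)

  if (use_exact) {
    pg <- group_prob(sc, ages)            # 18 x 7
    # P(score7 = k | age) by sequential convolution of 7 Bernoullis
    p_ge4 <- p_ge5 <- mean7_a <- numeric(length(ages))
    for (i in seq_along(ages)) {
      pmf <- 1
      for (g in 1:7) pmf <- convolve_bernoulli(pmf, pg[i, g])
      p_ge4[i] <- sum(pmf[5:8])           # pmf indices 1..8 are scores 0..7
      p_ge5[i] <- sum(pmf[6:8])
      mean7_a[i] <- sum(pg[i, ])
    }
    mdd7 <- sum(pi_a * p_ge4)
    mdd8 <- sum(pi_a * (p_bf * p_ge4 + (1 - p_bf) * p_ge5))
    mean7 <- sum(pi_a * mean7_a)
    mean8 <- mean7 + sum(pi_a * p_bf)
    method <- "exact"
  } else {
    stopifnot(is.numeric(n_mc), n_mc >= 1)
    sim <- with_seed(seed, {
      a <- sample(ages, n_mc, replace = TRUE, prob = pi_a)
      u <- if (sc$child_heterogeneity_sd > 0)
        stats::rnorm(n_mc, 0, sc$child_heterogeneity_sd) else numeric(n_mc)
      eta <- outer(sc$group_logit_slope * a + u,
                   sc$group_logit_intercepts, "+")
      s7 <- rowSums(stats::runif(7L * n_mc) < expit(eta))
      bf <- stats::runif(n_mc) < bf_prob(sc, a)
      list(a = a, s7 = s7, bf = bf)
    })
    mdd7 <- mean(sim$s7 >= 4)
    mdd8 <- mean(sim$s7 + sim$bf >= 5)
    mean7 <- mean(sim$s7)
    mean8 <- mean(sim$s7 + sim$bf)
    method <- "monte-carlo"
  }

  in_band <- function(lo, hi) {
    sel <- ages >= lo & ages <= hi
    if (sum(pi_a[sel]) == 0) return(NA_real_)
    sum(pi_a[sel] * p_bf[sel]) / sum(pi_a[sel])
  }
  list(mdd7_true = mdd7, mdd8_true = mdd8,
       bf_6_11_true = in_band(6, 11), bf_12_23_true = in_band(12, 23),
       mean7_true = mean7, mean8_true = mean8, method = method)
}

# pmf of (X + Bernoulli(p)) given pmf of X on 0..k
convolve_bernoulli <- function(pmf, p) {
  c(pmf * (1 - p), 0) + c(0, pmf * p)
}

#' Write a cohort to delimited text
#'
#' Writes the canonical column layout produced by [generate_cohort()]; the
#' result round-trips exactly through [read_child_records()] with
#' [default_mapping()].
#'
#' @param records cohort `data.frame`.
#' @param path output file path.
#' @param sep field separator (`","` or `"\t"`).
#' @return `path`, invisibly.
#' @export
write_child_records <- function(records, path, sep = ",") {
  cols <- intersect(cohort_columns(), names(records))
  extra <- setdiff(names(records), cols)
  utils::write.table(records[, c(cols, extra)], path, sep = sep,
                     row.names = FALSE, quote = TRUE, qmethod = "double")
  invisible(path)
}
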