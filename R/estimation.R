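# normal 97.5% quantile; PSU counts are large in practice, so no t quantile
Z975 <- 1.959964

new_svy_estimate <- function(estimate, se, ci_low, ci_high, n, n_psu,
                             method, scale) {
  structure(list(estimate = estimate, se = se, ci_low = ci_low,
                 ci_high = ci_high, n = as.integer(n),
                 n_psu = as.integer(n_psu), method = method, scale = scale),
            class = "svy_estimate")
}

#' @export
print.svy_estimate <- function(x, digits = 4, ...) {
  cat(sprintf("%s estimate: %s (SE %s), 95%% CI [%s, %s], n = %d, PSUs = %d, CI method: %s\n",
              x$scale, format(x$estimate, digits = digits),
              format(x$se, digits = digits),
              format(x$ci_low, digits = digits),
              format(x$ci_high, digits = digits),
              x$n, x$n_psu, x$method))
  invisible(x)
}

# Between-PSU variance of the linearized variate z, stratified first-stage
# approximation: sum_h n_h/(n_h-1) sum_c (Z_hc - mean_h)^2 over cluster
# totals Z_hc.  Singleton-PSU strata either abort or contribute their
# squared deviation from the grand PSU mean (factor 1).
taylor_variance <- function(z, clusters, strata, singleton = "fail") {
  f <- interaction(as.character(strata), as.character(clusters),
                   drop = TRUE, lex.order = TRUE)
  tot <- rowsum(z, f)[, 1]
  st_of <- vapply(split(as.character(strata), f), `[`, "", 1)
  v <- 0
  singles <- character(0)
  for (h in unique(st_of)) {
    th <- tot[st_of == h]
    n_h <- length(th)
    if (n_h >= 2) {
      v <- v + n_h / (n_h - 1) * sum((th - mean(th))^2)
    } else {
      singles <- c(singles, h)
    }
  }
  if (length(singles)) {
    if (identical(singleton, "centered")) {
      grand <- mean(tot)
      v <- v + sum((tot[st_of %in% singles] - grand)^2)
    } else {
      stop("stratum ", paste(singles, collapse = ", "),
           " contains a single PSU; no variance contribution is estimable ",
           "(use singleton = \"centered\" to center singletons at the ",
           "grand PSU mean)", call. = FALSE)
    }
  }
  v
}

# Shared ratio-estimator engine for weighted proportions and means.
# Subgroups are handled as estimation domains: out-of-domain records stay
# in the design with a zero linearized variate, they are never dropped.
svy_stat <- function(y, weights, clusters, strata, domain = NULL,
                     scale = c("proportion", "mean"),
                     method = c("logit", "wald"), singleton = "fail") {
  scale <- match.arg(scale)
  method <- match.arg(method)
  n_all <- length(y)
  if (length(weights) != n_all || length(clusters) != n_all)
    stop("y, weights and clusters must have equal length", call. = FALSE)
  if (is.null(strata)) strata <- rep("all", n_all)
  if (length(strata) != n_all)
    stop("strata must match the length of y", call. = FALSE)
  if (any(!is.finite(weights)) || any(weights <= 0))
    stop("weights must be positive and finite", call. = FALSE)
  if (is.null(domain)) domain <- rep(TRUE, n_all)
  n_psu <- length(unique(paste(strata, clusters, sep = "\r")))
  n_dom <- sum(domain)
  if (n_dom == 0)
    return(new_svy_estimate(NA_real_, NA_real_, NA_real_, NA_real_,
                            0L, n_psu, method, scale))
  if (any(is.na(y[domain])))
    stop("y contains missing values inside the domain", call. = FALSE)

  w_d <- sum(weights[domain])
  est <- sum(weights[domain] * y[domain]) / w_d
  z <- numeric(n_all)
  z[domain] <- weights[domain] * (y[domain] - est) / w_d

  se <- if (all(z == 0)) 0 else
    sqrt(taylor_variance(z, clusters, strata, singleton))

  if (scale == "mean") method <- "wald"
  if (se == 0) {
    ci <- c(est, est)
  } else if (method == "logit") {
    l <- stats::qlogis(est)
    se_l <- se / (est * (1 - est))
    ci <- stats::plogis(l + c(-1, 1) * Z975 * se_l)
  } else {
    ci <- est + c(-1, 1) * Z975 * se
  }
  new_svy_estimate(est, se, ci[1], ci[2], n_dom, n_psu, method, scale)
}

#' Design-weighted prevalence with Taylor-linearized variance
#'
#' Estimates a population proportion \eqn{p = \sum w_i y_i / \sum w_i}
#' under a stratified cluster design.  The variance is the first-stage
#' between-PSU Taylor linearization of the ratio estimator: within each
#' stratum the linearized variate \eqn{z_i = w_i (y_i - \hat p) / \sum w}
#' is totalled by cluster and its between-cluster variability, scaled by
#' \eqn{n_h/(n_h - 1)}, is summed over strata.  The default 95% confidence
#' interval is computed on the logit scale and back-transformed, which
#' keeps it inside \eqn{[0, 1]}; a symmetric Wald interval is available.
#' Degenerate estimates (constant outcome, so SE 0) collapse the interval
#' to the point.
#'
#' @param y 0/1 outcome vector.
#' @param weights positive sampling weights (scale-invariant: multiplying
#'   all weights by a constant changes nothing).
#' @param clusters PSU identifiers; defaults to one PSU per record
#'   (independent sampling).
#' @param strata stratum identifiers, or `NULL` for one implicit stratum.
#' @param method `"logit"` (default) or `"wald"` interval.
#' @param singleton how to treat strata with a single PSU: `"fail"`
#'   (default, explicit error) or `"centered"` (deviation from the grand
#'   PSU mean).
#' @return A `svy_estimate`: `estimate`, `se`, `ci_low`, `ci_high`, `n`,
#'   `n_psu`, `method`, `scale`.
#' @export
#' @examples
#' weighted_proportion(c(1, 0, 1, 0), rep(1, 4))
weighted_proportion <- function(y, weights, clusters = seq_along(y),
                                strata = NULL, method = c("logit", "wald"),
                                singleton = "fail") {
  y <- as.numeric(y)
  if (any(!y[!is.na(y)] %in% c(0, 1)))
    stop("y must be binary (0/1) for a proportion", call. = FALSE)
  svy_stat(y, weights, clusters, strata, scale = "proportion",
           method = match.arg(method), singleton = singleton)
}

#' Design-weighted mean with Taylor-linearized standard error
#'
#' Same estimator and variance as [weighted_proportion()] applied to a
#' bounded numeric outcome (here, diversity scores in 0-8); the interval
#' is Wald on the natural scale.
#'
#' @inheritParams weighted_proportion
#' @param y numeric outcome vector.
#' @return A `svy_estimate` with `scale = "mean"`.
#' @export
#' @examples
#' weighted_mean(c(2, 4), rep(1, 2), clusters = c("a", "b"))
weighted_mean <- function(y, weights, clusters = seq_along(y),
                          strata = NULL, singleton = "fail") {
  svy_stat(as.numeric(y), weights, clusters, strata, scale = "mean",
           singleton = singleton)
}

#' Age-band domain estimates
#'
#' Estimates an indicator within age bands (default 6-11 and 12-23
#' completed months, the standard reporting bands for continued
#' breastfeeding).  Each band is treated as an estimation domain: the full
#' design is retained and out-of-band records enter the variance with a
#' zero linearized variate rather than being dropped, so the point
#' estimate equals the naive subset ratio but the SE reflects the design.
#'
#' @param records record `data.frame` with `age_months`, design columns
#'   and the outcome.
#' @param scores optional [score_cohort()] output aligned with `records`,
#'   needed when `outcome` is `"mdd7"` or `"mdd8"`.
#' @param bands named list of `c(low, high)` integer age bounds; must
#'   partition 6..23.
#' @param outcome `"breastfed"` (default), `"mdd7"` or `"mdd8"`.
#' @inheritParams weighted_proportion
#' @return Named list of `svy_estimate`, one per band (empty bands give a
#'   flagged estimate with `n = 0`).
#' @export
estimate_by_ageband <- function(records, scores = NULL,
                                bands = list("6-11" = c(6, 11),
                                             "12-23" = c(12, 23)),
                                outcome = c("breastfed", "mdd7", "mdd8"),
                                method = c("logit", "wald"),
                                singleton = "fail") {
  outcome <- match.arg(outcome)
  method <- match.arg(method)
  covered <- sort(unlist(lapply(bands, function(b) seq(b[1], b[2]))))
  if (!identical(as.integer(covered), 6:23))
    stop("age bands must partition 6..23 months", call. = FALSE)
  y <- if (outcome == "breastfed") as.numeric(records$breastfed)
       else as.numeric(scores[[outcome]])
  out <- lapply(bands, function(b) {
    dom <- records$age_months >= b[1] & records$age_months <= b[2]
    svy_stat(y, records$weight, records$cluster_id, records$stratum_id,
             domain = dom, scale = "proportion", method = method,
             singleton = singleton)
  })
  out
}

#' Do two 95% confidence intervals overlap?
#'
#' Closed-interval test: intervals sharing only an endpoint count as
#' overlapping.
#'
#' @param a,b `svy_estimate` objects on the same scale, or numeric
#'   `c(low, high)` interval endpoints.
#' @return `TRUE` if the intervals intersect.
#' @export
#' @examples
#' ci_overlap(c(43.4, 51.2), c(35.0, 42.1))  # FALSE
ci_overlap <- function(a, b) {
  as_int <- function(x) {
    if (inherits(x, "svy_estimate")) c(x$ci_low, x$ci_high, scale = x$scale)
    else if (is.numeric(x) && length(x) == 2) c(sort(x), scale = NA)
    else stop("expected a svy_estimate or a numeric (low, high) pair",
              call. = FALSE)
  }
  ia <- as_int(a); ib <- as_int(b)
  if (inherits(a, "svy_estimate") && inherits(b, "svy_estimate") &&
      !identical(a$scale, b$scale))
    stop("cannot compare intervals on different scales", call. = FALSE)
  la <- as.numeric(ia[1]); ha <- as.numeric(ia[2])
  lb <- as.numeric(ib[1]); hb <- as.numeric(ib[2])
  la <= hb && lb <= ha
}
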