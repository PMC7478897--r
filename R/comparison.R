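#' Arithmetic difference between the two indicator definitions
#'
#' The headline comparison statistic: MDD-8 prevalence minus MDD-7
#' prevalence, in percentage points.  Because meeting MDD-8 implies
#' meeting MDD-7 child by child, the difference is never positive when
#' both inputs come from the same cohort.
#'
#' @param mdd8_pct,mdd7_pct prevalences on the percent scale (0-100);
#'   vectorised.
#' @return `mdd8_pct - mdd7_pct` in percentage points (unrounded; report
#'   to 1 decimal).
#' @export
#' @examples
#' difference_pp(38.5, 47.4)  # -8.9
difference_pp <- function(mdd8_pct, mdd7_pct) {
  stopifnot(is.numeric(mdd8_pct), is.numeric(mdd7_pct))
  if (any(mdd8_pct < 0 | mdd8_pct > 100 | mdd7_pct < 0 | mdd7_pct > 100,
          na.rm = TRUE))
    stop("prevalences must be on the percent scale (0-100)", call. = FALSE)
  mdd8_pct - mdd7_pct
}

pct <- function(e) {
  # rescale a proportion-scale svy_estimate to percent for reporting
  new_svy_estimate(100 * e$estimate, 100 * e$se, 100 * e$ci_low,
                   100 * e$ci_high, e$n, e$n_psu, e$method, e$scale)
}

#' Assemble the full indicator comparison for one survey
#'
#' Runs the whole design-based analysis for one scored cohort:
#' breastfeeding prevalence by age band (6-11, 12-23 months), MDD-7 and
#' MDD-8 prevalence, mean 7- and 8-group scores, the MDD-8 minus MDD-7
#' difference in percentage points (computed from unrounded estimates),
#' a flag for non-overlapping 95% CIs, and lowess age curves of the three
#' indicators.  Prevalences are reported on the percent scale.
#'
#' @param records cohort `data.frame` (design columns, age, breastmilk,
#'   food groups).
#' @param scores aligned [score_cohort()] output; computed from `records`
#'   when omitted.
#' @param label country/survey label (default taken from the records).
#' @param year survey year label.
#' @param method CI method passed to the estimators.
#' @param bandwidth lowess span for the age curves.
#' @inheritParams weighted_proportion
#' @return Object of class `country_comparison` with fields
#'   `country_label`, `survey_year`, `n`, `bf_6_11`, `bf_12_23`, `mdd7`,
#'   `mdd8` (percent-scale `svy_estimate`s), `mean7`, `mean8`,
#'   `difference_pp`, `ci_nonoverlap`, `curves`.
#' @seealso [rank_differences()], [write_comparison_table()]
#' @export
#' @examples
#' sc <- preset_scenarios()[["low-bf-high-diversity"]]
#' cohort <- generate_cohort(sc, seed = 7)
#' compare_country(cohort, year = "sim")
compare_country <- function(records, scores = NULL, label = NULL,
                            year = NA_character_,
                            method = c("logit", "wald"),
                            bandwidth = 0.7, singleton = "fail") {
  method <- match.arg(method)
  if (is.null(scores)) scores <- score_cohort(records)
  if (is.null(label))
    label <- if (!is.null(records$country_label))
      as.character(records$country_label[1]) else "unlabelled"
  w <- records$weight; cl <- records$cluster_id; st <- records$stratum_id
  bf_bands <- estimate_by_ageband(records, scores, outcome = "breastfed",
                                  method = method, singleton = singleton)
  mdd7 <- weighted_proportion(scores$mdd7, w, cl, st, method = method,
                              singleton = singleton)
  mdd8 <- weighted_proportion(scores$mdd8, w, cl, st, method = method,
                              singleton = singleton)
  mean7 <- weighted_mean(scores$score7, w, cl, st, singleton = singleton)
  mean8 <- weighted_mean(scores$score8, w, cl, st, singleton = singleton)
  structure(
    list(country_label = label, survey_year = year, n = nrow(records),
         bf_6_11 = pct(bf_bands[["6-11"]]), bf_12_23 = pct(bf_bands[["12-23"]]),
         mdd7 = pct(mdd7), mdd8 = pct(mdd8), mean7 = mean7, mean8 = mean8,
         difference_pp = difference_pp(100 * mdd8$estimate,
                                       100 * mdd7$estimate),
         ci_nonoverlap = !ci_overlap(mdd7, mdd8),
         curves = indicator_curves(records, scores, bandwidth)),
    class = "country_comparison")
}

fmt_ci <- function(e) sprintf("%.1f (%.1f, %.1f)", e$estimate, e$ci_low, e$ci_high)
fmt_mean <- function(e) sprintf("%.1f (%.2f)", e$estimate, e$se)

#' @export
print.country_comparison <- function(x, ...) {
  cat(sprintf("Dietary diversity comparison: %s %s (n = %d, PSUs = %d)\n",
              x$country_label, x$survey_year, x$n, x$mdd7$n_psu))
  cat("  breastmilk, prev. 24 h:  6-11 mo ", fmt_ci(x$bf_6_11),
      "   12-23 mo ", fmt_ci(x$bf_12_23), "\n", sep = "")
  cat("  MDD-7 (>=4 of 7): ", fmt_ci(x$mdd7), "%,  mean groups ",
      fmt_mean(x$mean7), "\n", sep = "")
  cat("  MDD-8 (>=5 of 8): ", fmt_ci(x$mdd8), "%,  mean groups ",
      fmt_mean(x$mean8), "\n", sep = "")
  cat(sprintf("  difference (MDD-8 - MDD-7): %.1f pp; 95%% CIs %s\n",
              x$difference_pp,
              if (x$ci_nonoverlap) "do not overlap" else "overlap"))
  invisible(x)
}

#' @export
coef.country_comparison <- function(object, ...) {
  c(bf_6_11 = object$bf_6_11$estimate, bf_12_23 = object$bf_12_23$estimate,
    mdd7 = object$mdd7$estimate, mdd8 = object$mdd8$estimate,
    mean7 = object$mean7$estimate, mean8 = object$mean8$estimate,
    difference_pp = object$difference_pp)
}

#' @export
summary.country_comparison <- function(object, ...) {
  print(object)
  cat(sprintf("  mean8 - mean7 = %.4f = weighted breastfed proportion\n",
              object$mean8$estimate - object$mean7$estimate))
  invisible(object)
}

#' @export
plot.country_comparison <- function(x, ...) {
  plot(x$curves, main = sprintf("%s %s", x$country_label, x$survey_year), ...)
}

#' @export
as.data.frame.country_comparison <- function(x, ...) {
  unpack <- function(e, nm) {
    out <- data.frame(e$estimate, e$ci_low, e$ci_high, e$se)
    names(out) <- paste0(nm, c("", "_lo", "_hi", "_se"))
    out
  }
  cbind(data.frame(country = x$country_label, survey_year = x$survey_year,
                   n = x$n),
        unpack(x$bf_6_11, "bf_6_11"), unpack(x$bf_12_23, "bf_12_23"),
        unpack(x$mdd7, "mdd7"), unpack(x$mean7, "mean7"),
        unpack(x$mdd8, "mdd8"), unpack(x$mean8, "mean8"),
        data.frame(difference_pp = x$difference_pp,
                   ci_nonoverlap = x$ci_nonoverlap))
}

#' Rank countries by the size of the definition gap
#'
#' Orders comparison rows by the absolute MDD-8 minus MDD-7 difference and
#' counts how many exceed 5 percentage points (strict inequality).
#'
#' @param rows a list of `country_comparison` objects, or a `data.frame`
#'   with columns `country` (or `country_label`) and `difference_pp`.
#' @return List: `largest` and `smallest` (each `list(country,
#'   difference_pp)`) and `n_gap_gt5`.
#' @export
#' @examples
#' rank_differences(data.frame(country = c("A", "B"),
#'                             difference_pp = c(-8.9, -1.4)))
rank_differences <- function(rows) {
  if (inherits(rows, "country_comparison")) rows <- list(rows)
  if (is.data.frame(rows)) {
    lab <- rows$country
    if (is.null(lab)) lab <- rows$country_label
    d <- rows$difference_pp
  } else {
    stopifnot(length(rows) >= 1,
              all(vapply(rows, inherits, TRUE, "country_comparison")))
    lab <- vapply(rows, `[[`, "", "country_label")
    d <- vapply(rows, `[[`, 0, "difference_pp")
  }
  if (length(d) == 0) stop("no comparison rows supplied", call. = FALSE)
  i_max <- which.max(abs(d))
  i_min <- which.min(abs(d))
  list(largest = list(country = lab[i_max], difference_pp = d[i_max]),
       smallest = list(country = lab[i_min], difference_pp = d[i_min]),
       n_gap_gt5 = sum(abs(d) > 5))
}

#' Write and re-read a formatted comparison table
#'
#' Writes rows in the conventional reporting layout: prevalences as
#' `"x.x (lo, hi)"`, means as `"m.m (se)"` with SE to 2 decimals, the
#' difference to 1 decimal.  [read_comparison_table()] parses the strings
#' back to numbers, losslessly at the printed precision.
#'
#' @param rows list of `country_comparison` objects (may be empty).
#' @param path output CSV path.
#' @return `path` invisibly (`write_comparison_table`); a `data.frame`
#'   (`read_comparison_table`).
#' @export
write_comparison_table <- function(rows, path) {
  cols <- c("country", "survey_year", "n", "bf_6_11", "bf_12_23",
            "mdd7_pct", "mean7", "mdd8_pct", "mean8", "difference_pp")
  if (length(rows) == 0) {
    df <- as.data.frame(matrix(character(0), ncol = length(cols),
                               dimnames = list(NULL, cols)))
  } else {
    stopifnot(all(vapply(rows, inherits, TRUE, "country_comparison")))
    df <- do.call(rbind, lapply(rows, function(x) data.frame(
      country = x$country_label, survey_year = x$survey_year, n = x$n,
      bf_6_11 = fmt_ci(x$bf_6_11), bf_12_23 = fmt_ci(x$bf_12_23),
      mdd7_pct = fmt_ci(x$mdd7), mean7 = fmt_mean(x$mean7),
      mdd8_pct = fmt_ci(x$mdd8), mean8 = fmt_mean(x$mean8),
      difference_pp = sprintf("%.1f", x$difference_pp))))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @param path CSV written by `write_comparison_table`.
#' @rdname write_comparison_table
#' @export
read_comparison_table <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (nrow(df) == 0) return(df)
  parse_ci <- function(s, nm) {
    m <- regmatches(s, regexec("^(-?[0-9.]+) \\((-?[0-9.]+), (-?[0-9.]+)\\)$", s))
    out <- data.frame(t(vapply(m, function(v) as.numeric(v[2:4]), numeric(3))))
    names(out) <- paste0(nm, c("", "_lo", "_hi"))
    out
  }
  parse_mean <- function(s, nm) {
    m <- regmatches(s, regexec("^(-?[0-9.]+) \\((-?[0-9.]+)\\)$", s))
    out <- data.frame(t(vapply(m, function(v) as.numeric(v[2:3]), numeric(2))))
    names(out) <- paste0(nm, c("", "_se"))
    out
  }
  cbind(data.frame(country = df$country, survey_year = df$survey_year,
                   n = as.integer(df$n)),
        parse_ci(df$bf_6_11, "bf_6_11"), parse_ci(df$bf_12_23, "bf_12_23"),
        parse_ci(df$mdd7_pct, "mdd7"), parse_mean(df$mean7, "mean7"),
        parse_ci(df$mdd8_pct, "mdd8"), parse_mean(df$mean8, "mean8"),
        data.frame(difference_pp = as.numeric(df$difference_pp)))
}
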