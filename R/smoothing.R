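#' Lowess curve of a binary indicator against age
#'
#' Classic locally weighted running-line smoother (tricube-weighted local
#' linear regression, no robustness iterations), pinned to one explicit
#' variant so outputs are reproducible: at each evaluation age \eqn{x_0}
#' the \eqn{\lceil f n \rceil} nearest observations by \eqn{|age - x_0|}
#' are selected (distance ties all included), given tricube weights
#' \eqn{(1 - (d/d_{max})^3)^3} on distance normalised by the largest
#' selected distance, and a weighted least-squares line is evaluated at
#' \eqn{x_0}.  The curve is evaluated at each distinct observed age, which
#' matches the monthly granularity of the data; the 0/1 microdata are
#' smoothed directly, without pre-aggregation to monthly proportions, and
#' no sampling weights are applied.
#'
#' Degenerate neighbourhoods fall back gracefully: when every selected
#' point sits at \eqn{x_0} (distance 0), or when all positive-weight
#' points share one age, the fit is the (weighted) mean.
#'
#' @param ages integer ages in months.
#' @param y numeric outcomes (0/1 indicators, though any numeric works).
#' @param bandwidth fraction of the data in each local neighbourhood, in
#'   (0, 1]; default 0.7.
#' @param indicator tag stored on the curve (`"breastfed"`, `"mdd7"`,
#'   `"mdd8"`, or any label).
#' @return Object of class `smoothed_curve`: `x` (strictly increasing
#'   evaluation ages), `yhat`, `bandwidth`, `indicator`, `n_points`.
#' @export
#' @examples
#' lowess_curve(rep(6:10, 4), rep(c(0, 1), 10), bandwidth = 0.7)
lowess_curve <- function(ages, y, bandwidth = 0.7, indicator = "y") {
  ages <- as.numeric(ages)
  y <- as.numeric(y)
  if (length(ages) != length(y))
    stop("ages and y must have equal length", call. = FALSE)
  if (anyNA(ages) || anyNA(y)) stop("missing values not allowed", call. = FALSE)
  if (!is.numeric(bandwidth) || length(bandwidth) != 1 ||
      bandwidth <= 0 || bandwidth > 1)
    stop("bandwidth must lie in (0, 1]", call. = FALSE)
  xs <- sort(unique(ages))
  if (length(xs) < 2)
    stop("need at least 2 distinct ages to define a span", call. = FALSE)
  n <- length(y)
  q <- ceiling(bandwidth * n)
  yhat <- vapply(xs, function(x0) {
    d <- abs(ages - x0)
    dq <- sort(d, partial = q)[q]
    sel <- which(d <= dq)
    if (dq == 0) return(mean(y[sel]))
    w <- (1 - (d[sel] / dq)^3)^3
    fit_local_line(ages[sel], y[sel], w, x0)
  }, numeric(1))
  structure(list(x = xs, yhat = yhat, bandwidth = bandwidth,
                 indicator = indicator, n_points = n),
            class = "smoothed_curve")
}

# Weighted least-squares line evaluated at x0; weighted mean when the
# positive-weight design is (numerically) concentrated on one age.
fit_local_line <- function(x, y, w, x0) {
  sw <- sum(w)
  xbar <- sum(w * x) / sw
  ybar <- sum(w * y) / sw
  sxx <- sum(w * (x - xbar)^2)
  if (sxx <= 1e-10 * sw * max(1, xbar^2)) return(ybar)
  beta <- sum(w * (x - xbar) * (y - ybar)) / sxx
  ybar + beta * (x0 - xbar)
}

#' @export
print.smoothed_curve <- function(x, ...) {
  cat(sprintf("Lowess curve (%s), bandwidth %g, %d observations\n",
              x$indicator, x$bandwidth, x$n_points))
  print(data.frame(age = x$x, yhat = round(x$yhat, 4)), row.names = FALSE)
  invisible(x)
}

#' Smoothed age curves for the three feeding indicators
#'
#' Fits [lowess_curve()] to breastfeeding, MDD-7 and MDD-8 status on a
#' common grid of distinct observed ages, unweighted (the smoothing
#' describes the age pattern of the sample, not a design-based estimate).
#'
#' @param records record `data.frame` with `age_months` and `breastfed`.
#' @param scores aligned [score_cohort()] output.
#' @param bandwidth lowess span fraction, default 0.7.
#' @return Object of class `mdd_curves`: list with elements `breastfed`,
#'   `mdd7`, `mdd8` (each a `smoothed_curve`).
#' @export
indicator_curves <- function(records, scores, bandwidth = 0.7) {
  if (nrow(records) != nrow(scores))
    stop("records and scores must align row-wise", call. = FALSE)
  a <- records$age_months
  structure(
    list(breastfed = lowess_curve(a, records$breastfed, bandwidth, "breastfed"),
         mdd7 = lowess_curve(a, as.numeric(scores$mdd7), bandwidth, "mdd7"),
         mdd8 = lowess_curve(a, as.numeric(scores$mdd8), bandwidth, "mdd8")),
    class = "mdd_curves")
}

#' Pointwise gap between two smoothed curves
#'
#' @param a,b `smoothed_curve` objects on identical age grids.
#' @return `data.frame` with `age` and `gap` (`a$yhat - b$yhat`).
#' @export
curve_gap <- function(a, b) {
  stopifnot(inherits(a, "smoothed_curve"), inherits(b, "smoothed_curve"))
  if (!isTRUE(all.equal(a$x, b$x)))
    stop("curves are evaluated on different age grids", call. = FALSE)
  data.frame(age = a$x, gap = a$yhat - b$yhat)
}

#' @param x an `mdd_curves` object.
#' @param main plot title.
#' @param ... further arguments passed to [graphics::matplot()].
#' @rdname indicator_curves
#' @export
plot.mdd_curves <- function(x, main = "Feeding indicators by age", ...) {
  m <- cbind(x$breastfed$yhat, x$mdd7$yhat, x$mdd8$yhat)
  graphics::matplot(x$breastfed$x, m, type = "l", lty = 1, lwd = 2,
                    col = c("grey40", "#1b7837", "#762a83"),
                    xlab = "Age (months)", ylab = "Proportion",
                    ylim = c(0, 1), main = main, ...)
  graphics::legend("topright", bty = "n", lwd = 2,
                   col = c("grey40", "#1b7837", "#762a83"),
                   legend = c("Breastmilk (prev. 24 h)",
                              "MDD-7 (≥4 of 7)", "MDD-8 (≥5 of 8)"))
  invisible(x)
}
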