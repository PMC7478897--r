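# Independent brute-force oracles, deliberately written in a different
# style from the package internals (explicit loops, no shared code paths).

# Textbook Taylor linearization of a ratio estimator, term by term:
# cluster totals formed explicitly, stratum factors applied one stratum
# at a time.
brute_taylor_se <- function(y, w, cl, st) {
  est <- sum(w * y) / sum(w)
  z <- w * (y - est) / sum(w)
  v <- 0
  for (h in unique(st)) {
    cls <- unique(cl[st == h])
    n_h <- length(cls)
    totals <- numeric(n_h)
    for (j in seq_along(cls)) {
      totals[j] <- sum(z[st == h & cl == cls[j]])
    }
    zbar <- sum(totals) / n_h
    ssq <- 0
    for (j in seq_along(cls)) ssq <- ssq + (totals[j] - zbar)^2
    v <- v + n_h / (n_h - 1) * ssq
  }
  sqrt(v)
}

# Stratified delete-one-cluster jackknife for the same ratio estimator:
# remaining clusters in the deleted cluster's stratum are reweighted by
# n_h / (n_h - 1).
jackknife_se <- function(y, w, cl, st) {
  theta_hat <- sum(w * y) / sum(w)
  v <- 0
  for (h in unique(st)) {
    cls <- unique(cl[st == h])
    n_h <- length(cls)
    for (drop_cl in cls) {
      w_rep <- w
      w_rep[st == h & cl == drop_cl] <- 0
      idx <- st == h & cl != drop_cl
      w_rep[idx] <- w_rep[idx] * n_h / (n_h - 1)
      theta_rep <- sum(w_rep * y) / sum(w_rep)
      v <- v + (n_h - 1) / n_h * (theta_rep - theta_hat)^2
    }
  }
  sqrt(v)
}

# Single-point lowess oracle: neighbour selection, tricube weights and the
# closed-form weighted-least-squares line, step by step.
hand_lowess_point <- function(ages, y, f, x0) {
  n <- length(y)
  q <- ceiling(f * n)
  d <- abs(ages - x0)
  dq <- sort(d)[q]
  keep <- d <= dq
  xs <- ages[keep]; ys <- y[keep]; ds <- d[keep]
  wts <- (1 - (ds / dq)^3)^3
  sw <- sum(wts)
  mx <- sum(wts * xs) / sw
  my <- sum(wts * ys) / sw
  b <- sum(wts * (xs - mx) * (ys - my)) / sum(wts * (xs - mx)^2)
  a <- my - b * mx
  a + b * x0
}

# Re-count a cohort's scores one child and one group at a time.
recount_scores <- function(records) {
  out <- data.frame(score7 = integer(nrow(records)),
                    score8 = integer(nrow(records)),
                    mdd7 = logical(nrow(records)),
                    mdd8 = logical(nrow(records)))
  gcols <- c("grains", "legumes", "dairy", "flesh", "eggs",
             "vita_fruit_veg", "other_fruit_veg")
  for (i in seq_len(nrow(records))) {
    s <- 0L
    for (g in gcols) if (records[[g]][i] == 1L) s <- s + 1L
    s8 <- s + as.integer(records$breastfed[i] == 1L)
    out$score7[i] <- s
    out$score8[i] <- s8
    out$mdd7[i] <- s >= 4
    out$mdd8[i] <- s8 >= 5
  }
  out
}
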