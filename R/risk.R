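#' Pooled mean seizure rate with Poisson uncertainty
#'
#' The mean seizure rate over a window is the pooled event count across
#' experiments divided by the pooled exposure (number of experiments times
#' window length).  Treating seizure initiation as a Poisson process, the
#' variance of the count equals the count, so the rate uncertainty is
#' `sqrt(n_events) / exposure`.
#'
#' @param timelines nonempty list of [experiment_timeline()] objects.
#' @param window numeric `c(t0, t1)` in seconds, half-open `[t0, t1)`.
#' @return An object of class `rate_estimate`: list with `rate` and
#'   `uncertainty` (seizures/hour), `n_events`, `exposure_h`.
#' @export
mean_rate <- function(timelines, window) {
  if (!length(timelines)) stop("no timelines supplied", call. = FALSE)
  stopifnot(length(window) == 2, window[2] > window[1])
  n <- sum(vapply(timelines, count_events, integer(1), window = window))
  exposure_h <- length(timelines) * (window[2] - window[1]) / 3600
  structure(list(rate = n / exposure_h,
                 uncertainty = sqrt(n) / exposure_h,
                 n_events = n, exposure_h = exposure_h),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("<rate_estimate> %.3g +/- %.2g seizures/h (%d events / %g h)\n",
              x$rate, x$uncertainty, x$n_events, x$exposure_h))
  invisible(x)
}

#' One-degree-of-freedom chi-square test for two Poisson counts
#'
#' For two counts observed over equal exposures, under the null of equal
#' rates the statistic `(n1 - n2)^2 / (n1 + n2)` is asymptotically
#' chi-square with 1 df (the Poisson variance of each count equals the
#' count).  The closed form requires equal exposures; unequal exposures are
#' rejected rather than approximated.
#'
#' @param n1,n2 non-negative event counts.
#' @param exposure1_h,exposure2_h exposures in hours; must be equal.
#' @return list with `chi2` and `p` (upper-tail, 1 df).  Both counts zero
#'   gives `chi2 = 0`, `p = 1`.
#' @export
poisson_rate_test <- function(n1, n2, exposure1_h = 1, exposure2_h = 1) {
  stopifnot(n1 >= 0, n2 >= 0)
  if (!isTRUE(all.equal(exposure1_h, exposure2_h)))
    stop("unequal exposures are not supported by the closed-form test",
         call. = FALSE)
  if (n1 + n2 == 0) return(list(chi2 = 0, p = 1))
  chi2 <- (n1 - n2)^2 / (n1 + n2)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Chi-square test for two classified proportions with Poisson uncertainty
#'
#' For proportions `p_i = k_i / n_i` of seizures classified as similar, the
#' Poisson uncertainty on each is `u_i = sqrt(k_i) / n_i`.  The statistic is
#' `(p1 - p2)^2 / (u1^2 + u2^2)`, referred to chi-square with 1 df.
#'
#' @param k1,n1,k2,n2 successes and totals, `0 <= k <= n`, `n >= 1`.
#' @return list with `p1`, `u1`, `p2`, `u2`, `chi2`, `p`.  If both
#'   uncertainties vanish, `p = 1` when the proportions agree and `p = 0`
#'   otherwise.
#' @export
proportion_test <- function(k1, n1, k2, n2) {
  if (n1 < 1 || n2 < 1) stop("group totals must be >= 1", call. = FALSE)
  stopifnot(k1 >= 0, k1 <= n1, k2 >= 0, k2 <= n2)
  p1 <- k1 / n1; p2 <- k2 / n2
  u1 <- sqrt(k1) / n1; u2 <- sqrt(k2) / n2
  den <- u1^2 + u2^2
  if (den == 0) {
    out <- if (p1 == p2) list(chi2 = 0, p = 1) else list(chi2 = Inf, p = 0)
  } else {
    chi2 <- (p1 - p2)^2 / den
    out <- list(chi2 = chi2, p = stats::pchisq(chi2, 1, lower.tail = FALSE))
  }
  c(list(p1 = p1, u1 = u1, p2 = p2, u2 = u2), out)
}

#' Number of experiments at risk of seizing at a time point
#'
#' An experiment is at risk at time `t` if it had no seizure onset in the
#' preceding 5 minutes.  The interval is open on both ends, `(t - 300, t)`:
#' an onset at exactly `t` does not remove the experiment at `t`, so every
#' first event of a burst sees a positive at-risk count.
#'
#' @param timelines list of [experiment_timeline()] objects.
#' @param t_s time in seconds.
#' @param risk_window_s length of the preceding exclusion window (default
#'   300 s).
#' @return integer number of at-risk experiments.
#' @export
at_risk_count <- function(timelines, t_s, risk_window_s = 300) {
  sum(vapply(timelines, function(tl) {
    !any(tl$onsets_s > t_s - risk_window_s & tl$onsets_s < t_s)
  }, logical(1)))
}

# Epanechnikov kernel, unit mass on [-1, 1].
epanechnikov <- function(u) ifelse(abs(u) <= 1, 0.75 * (1 - u^2), 0)

#' Kernel-smoothed Nelson-Aalen estimate of the seizure hazard
#'
#' The hazard rate at time `t` is estimated by smoothing the Nelson-Aalen
#' increments with an Epanechnikov kernel:
#' \deqn{\hat h(t) = \sum_i K_b(t - T_i) / Y(T_i), \quad
#'       \widehat{var}(t) = \sum_i K_b(t - T_i)^2 / Y(T_i)^2,}
#' where the `T_i` are seizure onsets (hours relative to injection start),
#' `Y` is the at-risk count from [at_risk_count()], `K_b(u) = K(u/b)/b`,
#' and the bandwidth is `b = 5 / sqrt(N)` hours with `N` the number of
#' contributing events.  Events within 5 minutes of a prior onset in the
#' same experiment are treated as the same ictal episode and excluded (with
#' a warning); no boundary correction is applied at the window edges, so the
#' hazard is under-estimated within one bandwidth of -3 h and +5 h.
#'
#' @param timelines list of [experiment_timeline()] objects.
#' @param grid_step_h grid spacing in hours (default 1 minute).
#' @param range_h evaluation range in hours, default `c(-3, 5)`.
#' @param risk_window_s at-risk exclusion window in seconds (default 300).
#' @return An object of class `hazard_curve`: list with `grid_t_h`,
#'   `hazard` (per hour), `variance`, `bandwidth_h`, `n_events_used`.
#' @export
nelson_aalen_hazard <- function(timelines, grid_step_h = 1 / 60,
                                range_h = c(-3, 5), risk_window_s = 300) {
  events_h <- numeric(); y <- numeric(); n_dropped <- 0L
  for (tl in timelines) {
    t <- tl$onsets_s
    t <- t[t >= range_h[1] * 3600 & t <= range_h[2] * 3600]
    if (!length(t)) next
    # same-episode chaining: compare to the last *kept* onset
    keep <- rep(TRUE, length(t))
    last <- t[1]
    for (i in seq_along(t)[-1]) {
      keep[i] <- (t[i] - last) > risk_window_s
      if (keep[i]) last <- t[i]
    }
    n_dropped <- n_dropped + sum(!keep)
    t <- t[keep]
    events_h <- c(events_h, t / 3600)
    y <- c(y, vapply(t, function(ti)
      at_risk_count(timelines, ti, risk_window_s), numeric(1)))
  }
  if (n_dropped > 0)
    warning(sprintf(
      "%d event(s) within %g s of a prior onset excluded from the hazard",
      n_dropped, risk_window_s), call. = FALSE)
  if (!length(events_h))
    stop("no events in the evaluation range; hazard undefined", call. = FALSE)
  if (any(y == 0)) {
    warning(sprintf("%d event(s) with zero at-risk count excluded",
                    sum(y == 0)), call. = FALSE)
    events_h <- events_h[y > 0]; y <- y[y > 0]
  }
  n <- length(events_h)
  b <- 5 / sqrt(n)
  grid <- seq(range_h[1], range_h[2], by = grid_step_h)
  u <- outer(grid, events_h, "-") / b
  kb <- epanechnikov(u) / b
  hazard <- as.numeric(kb %*% (1 / y))
  variance <- as.numeric(kb^2 %*% (1 / y^2))
  structure(list(grid_t_h = grid, hazard = hazard, variance = variance,
                 bandwidth_h = b, n_events_used = n),
            class = "hazard_curve")
}

#' @export
print.hazard_curve <- function(x, ...) {
  cat(sprintf(
    "<hazard_curve> %d events, bandwidth %.3g h, grid [%g, %g] h (%d pts)\n",
    x$n_events_used, x$bandwidth_h, min(x$grid_t_h), max(x$grid_t_h),
    length(x$grid_t_h)))
  cat(sprintf("  peak hazard %.3g /h at t = %.2f h\n",
              max(x$hazard), x$grid_t_h[which.max(x$hazard)]))
  invisible(x)
}

#' Time of most significant divergence of the hazard from baseline
#'
#' Scans the experimental part of a hazard curve (`t >= 0`) for the grid
#' point where the hazard differs most significantly from a flat baseline
#' rate, using `chi2(t) = (h(t) - rate)^2 / (var(t) + uncertainty^2)` with
#' 1 df.  Grid points with zero denominator are skipped; ties break to the
#' earliest time.  Because the uncorrected kernel estimate is biased low
#' within one bandwidth of the window edges (see
#' [nelson_aalen_hazard()]), grid points beyond `t_max - bandwidth` are
#' excluded from the scan by default.
#'
#' Note the returned p-value is the tail probability of the chi-square at
#' the selected time; since the time is itself chosen as the argmax over
#' the grid, it is an optimistic (multiplicity-uncorrected) summary, not a
#' calibrated test of the null.
#'
#' @param curve a [nelson_aalen_hazard()] result.
#' @param baseline a [mean_rate()] estimate from the baseline window of the
#'   same cohort.
#' @param exclude_edge logical; drop grid points within one bandwidth of
#'   the upper window edge (default `TRUE`).
#' @return list with `t_h`, `chi2`, `p`.
#' @export
max_divergence_time <- function(curve, baseline, exclude_edge = TRUE) {
  sel <- curve$grid_t_h >= 0
  if (exclude_edge)
    sel <- sel & curve$grid_t_h <= max(curve$grid_t_h) - curve$bandwidth_h
  t <- curve$grid_t_h[sel]
  den <- curve$variance[sel] + baseline$uncertainty^2
  chi2 <- (curve$hazard[sel] - baseline$rate)^2 / den
  chi2[den == 0] <- NA_real_
  if (all(is.na(chi2)))
    stop("no grid point with positive variance", call. = FALSE)
  i <- which.max(chi2)   # which.max takes the first (earliest) maximum
  list(t_h = t[i], chi2 = chi2[i],
       p = stats::pchisq(chi2[i], 1, lower.tail = FALSE))
}
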