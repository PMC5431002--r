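test_that("mean_rate pools events and exposure with Poisson uncertainty", {
  tls <- read_events(example_events_path())
  kcl <- Filter(function(x) x$injection_type == "KCl", tls)
  pbs <- Filter(function(x) x$injection_type == "PBS", tls)
  base <- mean_rate(kcl, c(-10800, 0))
  expm <- mean_rate(kcl, c(0, 10800))
  expect_equal(base$rate, 20 / 72)
  expect_equal(base$uncertainty, sqrt(20) / 72)
  expect_equal(expm$rate, 48 / 72)
  expect_equal(expm$uncertainty, sqrt(48) / 72)
  for (w in list(c(-10800, 0), c(0, 10800))) {
    r <- mean_rate(pbs, w)
    expect_equal(r$rate, 0.2)
    expect_equal(r$uncertainty, sqrt(3) / 15)
  }
  zero <- mean_rate(list(tl(numeric(0))), c(0, 10800))
  expect_equal(zero$rate, 0)
  expect_equal(zero$uncertainty, 0)
  expect_error(mean_rate(list(), c(0, 3600)), "no timelines")
})

test_that("poisson_rate_test matches the count-based chi-square closed form", {
  res <- poisson_rate_test(20, 48, 72, 72)
  expect_equal(res$chi2, 28^2 / 68)
  expect_equal(res$p, 0.0006850369, tolerance = 1e-6)
  expect_equal(poisson_rate_test(3, 3), list(chi2 = 0, p = 1))
  expect_equal(poisson_rate_test(0, 0), list(chi2 = 0, p = 1))
  expect_error(poisson_rate_test(5, 5, 3, 6), "unequal exposures")
})

test_that("poisson_rate_test type-I error is calibrated at alpha = 0.05", {
  set.seed(914)
  lam <- 0.28 * 72   # expected events per 3-h-window x 24-experiment pool
  n1 <- rpois(2000, lam)
  n2 <- rpois(2000, lam)
  p <- mapply(function(a, b) poisson_rate_test(a, b)$p, n1, n2)
  expect_gte(mean(p < 0.05), 0.03)
  expect_lte(mean(p < 0.05), 0.07)
})

test_that("proportion_test reproduces the uncertainty-weighted chi-square", {
  expect_equal(proportion_test(104, 114, 17, 25)$p, 0.2157, tolerance = 1e-3)
  expect_equal(proportion_test(104, 114, 3, 7)$p, 0.0660, tolerance = 1e-3)
  same <- proportion_test(9, 12, 9, 12)
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)
  expect_equal(proportion_test(0, 5, 0, 9)$p, 1)   # both uncertainties zero
  expect_equal(proportion_test(0, 5, 0, 5)$p, 1)
  expect_error(proportion_test(1, 0, 1, 2), ">= 1")
})

test_that("proportion_test is symmetric and scales as documented", {
  a <- proportion_test(7, 20, 11, 30)
  b <- proportion_test(11, 30, 7, 20)
  expect_equal(a$chi2, b$chi2)
  expect_equal(a$p, b$p)
  # (k, n) -> (ck, cn) keeps the proportions but shrinks u^2 by 1/c,
  # so the statistic grows by the factor c
  for (c_fac in c(2, 5)) {
    sc <- proportion_test(7 * c_fac, 20 * c_fac, 11 * c_fac, 30 * c_fac)
    expect_equal(sc$p1, a$p1)
    expect_equal(sc$p2, a$p2)
    expect_equal(sc$chi2, c_fac * a$chi2)
  }
})

test_that("at_risk_count implements the open 5-minute exclusion interval", {
  empty <- lapply(1:10, function(i) tl(numeric(0), id = paste0("e", i)))
  expect_identical(at_risk_count(empty, 0), 10L)

  tls <- c(empty[1:3], list(tl(1000 - 100, id = "hit")))
  expect_identical(at_risk_count(tls, 1000), 3L)
  # an onset exactly at t does not remove the experiment at t
  tls2 <- list(tl(1000, id = "boundary"))
  expect_identical(at_risk_count(tls2, 1000), 1L)
  expect_identical(at_risk_count(tls2, 1000 + 1e-6), 0L)
  expect_identical(at_risk_count(tls2, 1299.9), 0L)
  # the interval is open at t - 300 too: exactly 5 min later, at risk again
  expect_identical(at_risk_count(tls2, 1300), 1L)

  set.seed(5)
  rand <- lapply(1:8, function(i)
    tl(sort(runif(rpois(1, 5), -10800, 18000)), id = paste0("r", i)))
  for (t in runif(40, -10800, 18000))
    expect_identical(at_risk_count(rand, t), brute_at_risk(rand, t))
})

test_that("Epanechnikov kernel has exact unit mass and compact support", {
  mass <- integrate(ictal:::epanechnikov, -1, 1, rel.tol = 1e-13)$value
  expect_equal(mass, 1, tolerance = 1e-12)
  expect_identical(ictal:::epanechnikov(c(-1.01, 1.01, 5)), c(0, 0, 0))
})

test_that("hazard estimator matches the single-event closed form", {
  h <- nelson_aalen_hazard(list(tl(3600)))
  expect_equal(h$n_events_used, 1L)
  expect_equal(h$bandwidth_h, 5)
  at1 <- which(abs(h$grid_t_h - 1) < 1e-9)
  expect_equal(h$hazard[at1], 0.75 / 5, tolerance = 1e-12)
  expect_equal(h$variance[at1], (0.75 / 5)^2, tolerance = 1e-12)
  expect_true(all(h$hazard >= 0) && all(h$variance >= 0))
  expect_error(nelson_aalen_hazard(list(tl(numeric(0)))), "no events")
})

test_that("hazard kernel support is compact and respects the at-risk count", {
  # 25 experiments with one event each at t = 1 h: N = 25, b = 1, Y = 25,
  # so the estimate is exactly K(t - 1) and vanishes outside [0, 2]
  tls <- lapply(1:25, function(i) tl(3600, id = paste0("e", i)))
  h <- nelson_aalen_hazard(tls)
  expect_equal(h$bandwidth_h, 1)
  expect_equal(h$hazard[h$grid_t_h < -1e-9 | h$grid_t_h > 2 + 1e-9],
               rep(0, sum(h$grid_t_h < -1e-9 | h$grid_t_h > 2 + 1e-9)))
  at1 <- which(abs(h$grid_t_h - 1) < 1e-9)
  expect_equal(h$hazard[at1], 0.75, tolerance = 1e-12)
})

test_that("within-episode events are excluded from the hazard with a warning", {
  tls <- list(tl(c(0, 200, 700)), tl(3600, id = "e2"))
  expect_warning(h <- nelson_aalen_hazard(tls), "excluded")
  expect_equal(h$n_events_used, 3L)  # 200 s follows 0 s within 300 s
})

test_that("hazard curve is continuous: adjacent jumps shrink with the grid", {
  set.seed(21)
  tls <- simulate_timeline(cohort_spec(30, 0.5, 2, seed = 77))
  jump <- vapply(c(1 / 20, 1 / 60, 1 / 240), function(step) {
    h <- suppressWarnings(nelson_aalen_hazard(tls, grid_step_h = step))
    max(abs(diff(h$hazard)))
  }, numeric(1))
  expect_true(all(diff(jump) < 0))
})

test_that("max divergence scan flags constructed and flat curves correctly", {
  flat <- structure(list(grid_t_h = seq(-3, 5, by = 0.25),
                         hazard = rep(0.4, 33), variance = rep(0.01, 33),
                         bandwidth_h = 0.5, n_events_used = 10),
                    class = "hazard_curve")
  base <- structure(list(rate = 0.4, uncertainty = 0.1, n_events = 16,
                         exposure_h = 40), class = "rate_estimate")
  res <- max_divergence_time(flat, base)
  expect_equal(res$chi2, 0)
  expect_equal(res$p, 1)
  expect_equal(res$t_h, 0)   # tie broken to the earliest time

  # zero denominator everywhere except one grid point: that point is the
  # only candidate and is returned
  spike <- flat
  spike$variance <- rep(0, 33)
  spike$variance[which(spike$grid_t_h == 2)] <- 0.01
  spike$hazard[which(spike$grid_t_h == 2)] <- 1.4
  base0 <- structure(list(rate = 0.4, uncertainty = 0, n_events = 0,
                          exposure_h = 1), class = "rate_estimate")
  res <- max_divergence_time(spike, base0)
  expect_equal(res$t_h, 2)
  expect_lt(res$p, 1e-6)
})

test_that("elevated cohorts put the divergence inside the injection window", {
  for (seed in c(101, 102, 103)) {
    tls <- simulate_timeline(cohort_spec(24, 0.28, 3, seed = seed))
    base <- mean_rate(tls, c(-10800, 0))
    h <- suppressWarnings(nelson_aalen_hazard(tls))
    res <- max_divergence_time(h, base)
    expect_gte(res$t_h, 0)
    expect_lte(res$t_h, 3 + h$bandwidth_h)
  }
})

test_that("divergence p-values separate elevated cohorts from null ones", {
  p_null <- vapply(1:12, function(r) {
    tls <- simulate_timeline(cohort_spec(24, 0.28, 1, seed = 500 + r))
    suppressWarnings(max_divergence_time(nelson_aalen_hazard(tls),
                                         mean_rate(tls, c(-10800, 0)))$p)
  }, numeric(1))
  p_elev <- vapply(1:12, function(r) {
    tls <- simulate_timeline(cohort_spec(24, 0.28, 3, seed = 500 + r))
    suppressWarnings(max_divergence_time(nelson_aalen_hazard(tls),
                                         mean_rate(tls, c(-10800, 0)))$p)
  }, numeric(1))
  expect_lt(median(p_elev), 0.005)
  expect_gt(median(p_null), 10 * median(p_elev))
  expect_gte(mean(p_null > p_elev), 0.75)
})
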