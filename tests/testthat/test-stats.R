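test_that("detrending removes exact trends and matches the OLS oracle", {
  yr <- 1990:2005
  expect_equal(detrend_linear(3 + 0.7 * yr, yr), rep(0, 16),
               tolerance = 1e-9)
  expect_error(detrend_linear(1:3), "at least 4")

  quad <- (yr - 1997)^2
  got <- detrend_linear(quad, yr)
  beta <- oracle_ols(quad, yr)
  expect_equal(got, quad - beta[1L] - beta[2L] * yr, tolerance = 1e-8)
  expect_lt(abs(mean(got)), 1e-10)
})

test_that("partial correlation reduces, saturates and matches the closed form", {
  set.seed(10)
  y <- rnorm(20); x <- rnorm(20); z <- rnorm(20)

  expect_equal(partial_correlation(y, x)$r, cor(y, x), tolerance = 1e-12)
  expect_equal(partial_correlation(x, x, z)$r, 1)

  pc <- partial_correlation(y, x, z)
  expect_equal(pc$r, oracle_partial_r1(y, x, z), tolerance = 1e-12)
  expect_equal(pc$df, 20L - 2L - 1L)

  # symmetric in (y, x)
  expect_equal(partial_correlation(x, y, z)$r, pc$r, tolerance = 1e-12)
})

test_that("ten-point seeded data matches the one-control closed form", {
  set.seed(77)
  y <- rnorm(10); x <- 0.5 * y + rnorm(10); z <- 0.3 * x + rnorm(10)
  pc <- partial_correlation(y, x, z)
  expect_equal(pc$r, oracle_partial_r1(y, x, z), tolerance = 1e-12)
})

test_that("collinear controls are rejected", {
  set.seed(12)
  y <- rnorm(15); x <- rnorm(15); z <- rnorm(15)
  expect_error(partial_correlation(y, x, cbind(z, 2 * z)), "collinear")
  expect_error(sensitivity_slope(y, cbind(x, x)), "collinear")
})

test_that("an irrelevant control barely moves the correlation", {
  set.seed(21)
  n <- 100
  deltas <- vapply(1:50, function(i) {
    y <- rnorm(n); x <- 0.4 * y + rnorm(n); z <- rnorm(n)
    abs(partial_correlation(y, x, z)$r - partial_correlation(y, x)$r)
  }, numeric(1L))
  expect_lt(max(deltas), 2 / sqrt(n))
})

test_that("subsampling degenerates, enumerates and converges correctly", {
  set.seed(31)
  y <- rnorm(17); x <- 0.6 * y + rnorm(17)
  z <- cbind(rnorm(17), rnorm(17))

  full <- partial_correlation(y, x, z)
  s_full <- subsample_partial_correlation(y, x, z, m = 17)
  expect_equal(s_full$sd, 0)
  expect_equal(s_full$mean, full$r, tolerance = 1e-12)

  # exhaustive 4-of-5 enumeration against an independent loop
  y5 <- rnorm(5); x5 <- rnorm(5)
  s5 <- subsample_partial_correlation(y5, x5, NULL, m = 4,
                                      method = "exhaustive")
  manual <- vapply(1:5, function(drop) cor(y5[-drop], x5[-drop]),
                   numeric(1L))
  expect_equal(sort(s5$draws), sort(manual), tolerance = 1e-12)
  expect_equal(s5$mean, mean(manual), tolerance = 1e-12)
  expect_equal(s5$sd, sd(manual), tolerance = 1e-12)

  # the study design: 14-of-17 subsets are enumerable
  s14 <- subsample_partial_correlation(y, x, z, m = 14)
  expect_equal(s14$method, "exhaustive")
  expect_equal(s14$n_draws, choose(17, 14))
  expect_equal(s14$n_draws, 680L)

  # subsample means converge monotonically to the full-sample r
  dev <- vapply(c(15L, 16L, 17L), function(m) {
    abs(subsample_partial_correlation(y, x, z, m = m)$mean - full$r)
  }, numeric(1L))
  expect_true(all(diff(dev) <= 1e-12))

  expect_error(subsample_partial_correlation(y, x, z, m = 5), "too small")
  expect_error(subsample_partial_correlation(y, x, z, m = 18), "exceed")
})

test_that("random subsampling is deterministic under a seed", {
  set.seed(8)
  y <- rnorm(25); x <- rnorm(25)
  a <- subsample_partial_correlation(y, x, NULL, m = 12, n_draws = 50,
                                     seed = 4, method = "random")
  b <- subsample_partial_correlation(y, x, NULL, m = 12, n_draws = 50,
                                     seed = 4, method = "random")
  expect_identical(a$draws, b$draws)
})

test_that("sensitivity slope recovers exact and noisy coefficients", {
  tt <- c(-3, -1, 0, 1, 3, -2, 2, 0, 1, -1)
  pp <- rep(c(1, -1), 5)
  cc <- rep(c(1, 1, -1, -1, 0), 2)
  y <- -2 * tt
  sl <- sensitivity_slope(y, cbind(T = tt, P = pp, C = cc))
  expect_equal(sl$gamma, -2, tolerance = 1e-10)
  expect_equal(sl$se, 0)

  set.seed(51)
  n <- 17
  fits <- lapply(1:30, function(i) {
    T_ <- rnorm(n); P_ <- rnorm(n); C_ <- rnorm(n)
    yy <- -2 * T_ + rnorm(n, 0, 0.8)
    list(fit = sensitivity_slope(yy, cbind(T_, P_, C_)),
         oracle = oracle_ols(yy, cbind(T_, P_, C_))[2L])
  })
  for (f in fits) {
    expect_equal(f$fit$gamma, unname(f$oracle), tolerance = 1e-9)
    expect_lt(abs(f$fit$gamma - (-2)) / f$fit$se, 5)
  }
  cover3 <- mean(vapply(fits, function(f) {
    abs(f$fit$gamma - (-2)) <= 3 * f$fit$se
  }, logical(1L)))
  expect_gte(cover3, 0.9)
})

test_that("slope test keeps its nominal type-I error", {
  set.seed(61)
  hits <- vapply(1:1000, function(i) {
    y <- rnorm(17)
    sensitivity_slope(y, cbind(rnorm(17), rnorm(17), rnorm(17)))$p < 0.05
  }, logical(1L))
  expect_gt(mean(hits), 0.03)
  expect_lt(mean(hits), 0.075)
})

test_that("period comparison handles draws, slopes and degenerate inputs", {
  mk <- function(mean, sd, n = 680) {
    structure(list(draws = rnorm(n, mean, sd), m = 14, n = 17,
                   n_draws = n, mean = mean, sd = sd,
                   method = "exhaustive", full = NULL),
              class = "subsample_dist")
  }
  set.seed(71)
  d1 <- mk(-0.42, 0.09); d1$mean <- mean(d1$draws); d1$sd <- sd(d1$draws)
  d2 <- mk(-0.64, 0.10); d2$mean <- mean(d2$draws); d2$sd <- sd(d2$draws)
  cmp <- compare_periods(d1, d2)
  expect_lt(cmp$p, 0.01)
  # Welch t-statistic oracle
  tstat <- (d1$mean - d2$mean) /
    sqrt(var(d1$draws) / d1$n_draws + var(d2$draws) / d2$n_draws)
  expect_equal(cmp$statistic, tstat, tolerance = 1e-9)
  # symmetry
  expect_equal(compare_periods(d2, d1)$p, cmp$p, tolerance = 1e-12)

  same <- mk(-0.5, 0); same$draws <- rep(-0.5, 680)
  expect_equal(compare_periods(same, same)$p, 1)

  s1 <- structure(list(gamma = -1.23, se = 0.76, p = NA, n = 17),
                  class = "sensitivity_slope")
  s2 <- structure(list(gamma = -2.06, se = 0.46, p = NA, n = 17),
                  class = "sensitivity_slope")
  z <- (-1.23 - (-2.06)) / sqrt(0.76^2 + 0.46^2)
  expect_equal(compare_periods(s1, s2)$p, 2 * pnorm(-abs(z)),
               tolerance = 1e-12)
})

test_that("moving windows count, stay flat and detect a coupling break", {
  yr <- 1979:2012
  set.seed(81)
  y <- rnorm(34); x <- rnorm(34)
  mw <- moving_window_correlation(yr, y, x, window = 15)
  expect_equal(nrow(mw$windows), 34 - 15 + 1)
  expect_equal(nrow(mw$windows), 20L)
  expect_error(moving_window_correlation(1979:1990, y[1:12], x[1:12],
                                         window = 15), "shorter")

  # stationary coupling: no trend in r for >= 90% of seeds
  flat <- vapply(1:100, function(i) {
    set.seed(1000 + i)
    xx <- rnorm(34)
    yy <- 0.8 * xx + rnorm(34, 0, 0.8)
    moving_window_correlation(yr, yy, xx, window = 15,
                              n_perm = 99, seed = i)$trend$p >= 0.05
  }, logical(1L))
  expect_gte(mean(flat), 0.9)

  # coupling switching sign at the break: declining r trend
  breaks <- vapply(1:100, function(i) {
    set.seed(2000 + i)
    xx <- rnorm(34)
    beta <- ifelse(yr < 1996, 0.8, -0.8)
    yy <- beta * xx + rnorm(34, 0, 0.6)
    tr <- moving_window_correlation(yr, yy, xx, window = 15,
                                    n_perm = 99, seed = i)$trend
    tr$slope < 0 && tr$p < 0.05
  }, logical(1L))
  expect_gte(mean(breaks), 0.8)
})

test_that("lagged correlation aligns years and reduces at lag zero", {
  yr <- 2000:2016
  set.seed(91)
  x <- rnorm(17)
  y <- c(NA, x[-17])  # y_t = x_{t-1}
  pc <- lagged_correlation(yr[-1L], y[-1L], x[-1L], lag = 1L,
                           detrend = FALSE)
  expect_equal(pc$r, 1)

  z <- rnorm(17)
  y2 <- 0.5 * x + rnorm(17)
  expect_equal(lagged_correlation(yr, y2, x, z, lag = 0L,
                                  detrend = FALSE)$r,
               partial_correlation(y2, x, z)$r, tolerance = 1e-12)

  # no lagged coupling in truth: lag-1/2 correlations stay null
  hits <- vapply(1:100, function(i) {
    set.seed(3000 + i)
    xx <- rnorm(30)
    yy <- 0.7 * xx + rnorm(30, 0, 0.7)  # contemporaneous only
    lagged_correlation(2000:2029, yy, xx, lag = 1L)$p < 0.05
  }, logical(1L))
  expect_lte(mean(hits), 0.1)
})

test_that("pixelwise maps reduce to scalars and recover a sign flip", {
  set.seed(95)
  yrs <- 2000:2013
  arr <- array(rnorm(3 * 4 * 14), c(3, 4, 14))
  self <- pixelwise_partial_correlation(arr, arr, years = yrs)
  expect_true(all(abs(self$r - 1) < 1e-9))

  y1 <- array(rnorm(14), c(1, 1, 14))
  x1 <- array(rnorm(14), c(1, 1, 14))
  z1 <- array(rnorm(14), c(1, 1, 14))
  m <- pixelwise_partial_correlation(y1, x1, list(z1), yrs)
  sc <- partial_correlation(detrend_linear(y1[1, 1, ], yrs),
                            detrend_linear(x1[1, 1, ], yrs),
                            detrend_linear(z1[1, 1, ], yrs))
  expect_equal(m$r[1, 1], sc$r, tolerance = 1e-12)
  expect_equal(m$p[1, 1], sc$p, tolerance = 1e-12)

  # beta flips sign across the break: difference map is negative
  x_e <- array(rnorm(3 * 4 * 10), c(3, 4, 10))
  x_l <- array(rnorm(3 * 4 * 10), c(3, 4, 10))
  y_e <- 0.9 * x_e + array(rnorm(3 * 4 * 10, 0, 0.4), c(3, 4, 10))
  y_l <- -0.9 * x_l + array(rnorm(3 * 4 * 10, 0, 0.4), c(3, 4, 10))
  m_e <- pixelwise_partial_correlation(y_e, x_e, years = 1:10)
  m_l <- pixelwise_partial_correlation(y_l, x_l, years = 1:10)
  dmap <- period_difference(m_e, m_l)
  expect_gte(mean(dmap < 0), 0.9)
})

test_that("null partial-correlation p-values are well calibrated", {
  set.seed(97)
  hits <- vapply(1:500, function(i) {
    y <- rnorm(17); x <- rnorm(17); z <- cbind(rnorm(17), rnorm(17))
    partial_correlation(y, x, z)$p < 0.05
  }, logical(1L))
  expect_gt(mean(hits), 0.025)
  expect_lt(mean(hits), 0.075)
})
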