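test_that("CSV and NOAA dialects parse, map sentinels and report bad lines", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("date,conc", "2001-01-01,370.12", "2001-01-02,-999.99",
               "2001-01-03,371.00"), p)
  s <- read_co2(p, "csv")
  expect_s3_class(s, "co2_series")
  expect_equal(nrow(s), 3L)
  expect_equal(sum(s$flag == "missing"), 1L)
  expect_equal(s$conc[1L], 370.12)

  p2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# station BRW", "1979 1 1 336.52 .", "1979 1 2 -999.99 .",
               "1979 1 3 336.71 ."), p2)
  s2 <- read_co2(p2, "noaa-insitu-daily")
  expect_equal(s2$conc[c(1L, 3L)], c(336.52, 336.71))
  expect_equal(s2$flag[2L], "missing")

  empty <- withr::local_tempfile()
  writeLines(character(0), empty)
  expect_error(read_co2(empty, "csv"), "empty")

  bad <- withr::local_tempfile()
  writeLines(c("date,conc", "2001-01-01,370.1", "garbage"), bad)
  expect_error(read_co2(bad, "csv"), "line 3")

  nonmono <- withr::local_tempfile()
  writeLines(c("1979 1 2 336.5 .", "1979 1 1 336.6 ."), nonmono)
  expect_error(read_co2(nonmono, "noaa-insitu-daily"), "monotone")
})

test_that("write/read round trip preserves concentrations to format precision", {
  sim <- generate_co2_series(small_params(seed = 11))
  p <- withr::local_tempfile(fileext = ".csv")
  write_co2(sim$series, p)
  back <- read_co2(p, "csv")
  ret <- sim$series$flag == "retained"
  expect_equal(back$conc[ret], sim$series$conc[ret], tolerance = 0.011)
  expect_true(all(back$flag[!ret] == "missing"))
})

test_that("fit recovers an exact linear trend with null harmonics", {
  s <- series_from_fun(2001:2004, function(t) 350 + 0.005 * t)
  fit <- fit_function(s)
  expect_equal(fit$poly[1L], 350, tolerance = 1e-6)
  expect_equal(fit$poly[2L], 0.005, tolerance = 1e-9)
  expect_lt(abs(fit$poly[3L]), 1e-10)
  expect_lt(max(abs(fit$harmonics)), 1e-8)
})

test_that("fit isolates a pure first harmonic", {
  s <- series_from_fun(2001:2004, function(t) 10 * sin(2 * pi * t / 365))
  fit <- fit_function(s)
  amp <- sqrt(rowSums(fit$harmonics^2))
  expect_equal(amp[[1L]], 10, tolerance = 1e-6)
  expect_lt(max(amp[2:4]), 1e-6)
})

test_that("noisy fit matches the normal-equations oracle and the truth", {
  years <- 2001:2006
  ax <- test_axis(years)
  true_poly <- c(360, 0.004, 1e-7)
  true_h <- c(6, -3)  # first-harmonic sine/cosine
  set.seed(42)
  conc <- true_poly[1L] + true_poly[2L] * ax$t + true_poly[3L] * ax$t^2 +
    true_h[1L] * sin(2 * pi * ax$t / 365) +
    true_h[2L] * cos(2 * pi * ax$t / 365) +
    rnorm(nrow(ax), 0, 0.5)
  s <- co2_series(ax$year, ax$doy, conc)
  fit <- fit_function(s)

  X <- cbind(ax$t, ax$t^2,
             sin(2 * pi * ax$t / 365), cos(2 * pi * ax$t / 365),
             sin(4 * pi * ax$t / 365), cos(4 * pi * ax$t / 365),
             sin(6 * pi * ax$t / 365), cos(6 * pi * ax$t / 365),
             sin(8 * pi * ax$t / 365), cos(8 * pi * ax$t / 365))
  beta <- oracle_ols(conc, X)
  got <- c(fit$poly, as.vector(t(fit$harmonics)))
  expect_equal(got, unname(beta), tolerance = 1e-6)
  # truth recovery: noise SE on the harmonic coefficients is
  # sigma * sqrt(2/n) ~ 0.015; allow 3 SE
  expect_equal(unname(got[4:5]), true_h, tolerance = 0.05)
})

test_that("reconstruction identity holds at every retained record", {
  sim <- generate_co2_series(truth_params(years = 1995:2004, seed = 2))
  rr <- reject_outliers(sim$series)
  ret <- rr$series[rr$series$flag == "retained", ]
  recon <- predict_fit(rr$fit, ret$t) + rr$fit$residuals
  expect_lt(max(abs(recon - ret$conc)), 1e-9)
})

test_that("outlier rejection leaves clean data alone and catches spikes", {
  s <- series_from_fun(2001:2004, function(t) {
    360 + 8 * sin(2 * pi * t / 365)
  })
  rr <- reject_outliers(s)
  expect_equal(rr$n_rejected, 0L)

  # one +50 ppm spike on a curve the fit otherwise captures
  set.seed(7)
  conc <- 360 + 8 * sin(2 * pi * s$t / 365) + rnorm(nrow(s), 0, 0.1)
  conc[500L] <- conc[500L] + 50
  s2 <- co2_series(s$year, s$doy, conc)
  rr2 <- reject_outliers(s2)
  expect_equal(rr2$n_rejected, 1L)
  expect_equal(which(s2$flag == "retained" & rr2$series$flag == "outlier"),
               500L)
})

test_that("truth-tagged spikes from the generator are flagged", {
  params <- small_params(seed = 21, ar1_rho = 0, ar1_sigma = 0.3,
                         gap_fraction = 0, outlier_rate = 0.003,
                         t_anom_sd = 0, drawdown_sigma = 0)
  sim <- generate_co2_series(params)
  rr <- reject_outliers(sim$series)
  flagged <- rr$series$t[rr$series$flag == "outlier"]
  expect_true(all(sim$truth$outlier_t %in% flagged))
})

test_that("FWHM filter normalises, preserves ramps and marks empty windows", {
  expect_equal(fwhm_filter(rep(5, 200), 30), rep(5, 200))

  ramp <- seq(0, 1, length.out = 400)
  sm <- fwhm_filter(ramp, 40)
  half <- ceiling(3 * 40 / (2 * sqrt(2 * log(2))))
  interior <- (half + 1):(400 - half)
  expect_lt(max(abs(sm[interior] - ramp[interior])), 1e-9)

  gappy <- c(rep(1, 50), rep(NA, 300), rep(2, 50))
  out <- fwhm_filter(gappy, 10)
  expect_true(anyNA(out))          # days with no data within 3 sigma
  expect_false(anyNA(out[1:50]))
})

test_that("FWHM filter is linear", {
  set.seed(5)
  x <- rnorm(300); y <- rnorm(300)
  lhs <- fwhm_filter(2 * x + 3 * y, 25)
  rhs <- 2 * fwhm_filter(x, 25) + 3 * fwhm_filter(y, 25)
  expect_lt(max(abs(lhs - rhs)), 1e-9)
})

test_that("filter attenuation of a 60-day sinusoid matches the convolution oracle", {
  t <- 0:999
  x <- sin(2 * pi * t / 60)
  got <- fwhm_filter(x, 46)
  want <- oracle_gauss_smooth(x, 46)
  interior <- 200:800
  att_got <- stats::sd(got[interior])
  att_want <- stats::sd(want[interior])
  expect_lt(abs(att_got - att_want) / att_want, 0.01)
  expect_lt(att_got, 0.25)  # strong attenuation of a 60-day wave at FWHM 46
})

test_that("decomposition of degenerate inputs is exact", {
  quad <- series_from_fun(2001:2004,
                          function(t) 340 + 0.004 * t + 1e-7 * t^2)
  d <- decompose_co2(quad)
  expect_lt(max(abs(d$axis$seasonal)), 1e-6)

  harm <- series_from_fun(2001:2004,
                          function(t) 5 * sin(2 * pi * t / 365))
  dh <- decompose_co2(harm)
  expect_lt(max(abs(dh$axis$seasonal -
                      5 * sin(2 * pi * dh$axis$t / 365))), 1e-6)
  expect_lt(diff(range(dh$axis$trend)), 1e-6)
})

test_that("decomposition recovers the imposed drawdown anomalies", {
  params <- truth_params(seed = 31, ar1_sigma = 0.3, gap_fraction = 0.02,
                         outlier_rate = 0)
  sim <- generate_co2_series(params)
  d <- decompose_co2(sim$series)
  scd <- scd_series(d, params$years)$scd
  expect_gt(cor(scd, sim$truth$drawdown_anom), 0.95)
  # detrended seasonal curve averages to ~0 over the record
  expect_lt(abs(mean(d$axis$seasonal, na.rm = TRUE)), 0.1)
})

test_that("gaps barely move the seasonal curve", {
  base <- small_params(seed = 8, ar1_sigma = 0.3, ar1_rho = 0.3,
                       outlier_rate = 0, gap_fraction = 0)
  sim <- generate_co2_series(base)
  d0 <- decompose_co2(sim$series)
  gapped <- small_params(seed = 8, ar1_sigma = 0.3, ar1_rho = 0.3,
                         outlier_rate = 0, gap_fraction = 0.05)
  simg <- generate_co2_series(gapped)
  dg <- decompose_co2(simg$series)
  rms <- sqrt(mean((d0$axis$seasonal - dg$axis$seasonal)^2, na.rm = TRUE))
  expect_lt(rms, 0.3)
})

test_that("weekly-path decomposition tracks the daily path", {
  params <- small_params(seed = 13, ar1_sigma = 0.3, ar1_rho = 0.3,
                         gap_fraction = 0, outlier_rate = 0)
  sim <- generate_co2_series(params)
  daily <- decompose_co2(sim$series)
  wk <- sim$series[seq(4L, nrow(sim$series), by = 7L), ]
  weekly <- co2_series(wk$year, wk$doy, wk$conc, wk$flag,
                       cadence = "weekly")
  dw <- decompose_co2(weekly)   # weekly cadence: no outlier rejection
  expect_equal(dw$n_outliers_removed, 0L)
  joint <- merge(daily$axis[, c("t", "seasonal")],
                 dw$axis[, c("t", "seasonal")], by = "t")
  rms <- sqrt(mean((joint$seasonal.x - joint$seasonal.y)^2, na.rm = TRUE))
  expect_lt(rms, 0.5)
})
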