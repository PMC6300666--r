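# Independent oracles and fixture builders shared across the test files.
# Every oracle re-derives its quantity by a different route than the
# implementation it checks.

# ordinary least squares by explicit normal equations
oracle_ols <- function(y, X) {
  X <- cbind(1, as.matrix(X))
  drop(solve(crossprod(X), crossprod(X, y)))
}

# direct discrete Gaussian-kernel convolution on a gap-free axis,
# written as an explicit loop
oracle_gauss_smooth <- function(x, fwhm) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  half <- as.integer(ceiling(3 * sigma))
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- max(1L, i - half):min(n, i + half)
    w <- exp(-(j - i)^2 / (2 * sigma^2))
    out[i] <- sum(w * x[j]) / sum(w)
  }
  out
}

# closed-form first-order partial correlation
oracle_partial_r1 <- function(y, x, z) {
  rxy <- stats::cor(y, x)
  rxz <- stats::cor(x, z)
  ryz <- stats::cor(y, z)
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}

# 365-day daily axis as a plain data frame (re-derived, not taken from
# the package internals)
test_axis <- function(years) {
  ax <- data.frame(year = rep(years, each = 365L),
                   doy = rep.int(1:365, length(years)))
  ax$t <- (ax$year - years[1L]) * 365 + ax$doy - 1
  ax
}

# daily co2_series whose concentration is a function of the day index t
series_from_fun <- function(years, f) {
  ax <- test_axis(years)
  co2_series(ax$year, ax$doy, f(ax$t), cadence = "daily")
}

# a decomposition object with a prescribed seasonal curve D(year, doy),
# for exercising the drawdown/phenology layer in isolation
fake_decomp <- function(years, d_fun) {
  ax <- test_axis(years)
  ax$trend <- 0
  ax$seasonal <- d_fun(ax$year, ax$doy)
  ax$short <- 0
  ax$long <- 0
  ax$edge <- FALSE
  structure(list(axis = ax, fit = NULL, series = NULL,
                 n_outliers_removed = 0L),
            class = "co2_decomposition")
}

# small, fast parameter set for desk-scale synthetic tests
small_params <- function(...) {
  truth_params(
    years = 1991:2008,
    break_year = 2000L,
    grid = list(lat_min = 50, lat_max = 80, nlat = 6L,
                lon_min = 0, lon_max = 360, nlon = 10L),
    ...
  )
}

# single-slice grid_field wrapper for matrices
static_field <- function(values, lat, lon, units = "degC",
                         name = "field") {
  grid_field(lat, lon, NULL, values, units, name)
}

# monthly temperature field with prescribed July/August slabs
monthly_field <- function(lat, lon, years, july, august, units = "degC",
                          name = "temperature") {
  tm <- expand.grid(month = c(7L, 8L), year = years)[, c("year", "month")]
  vals <- array(0, c(length(lat), length(lon), nrow(tm)))
  for (i in seq_len(nrow(tm))) {
    vals[, , i] <- if (tm$month[i] == 7L) july[[as.character(tm$year[i])]]
                   else august[[as.character(tm$year[i])]]
  }
  grid_field(lat, lon, tm, vals, units, name)
}
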