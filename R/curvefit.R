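#' Fit the trend + seasonal function to a CO2 series
#'
#' Least-squares fit of a quadratic polynomial (long-term trend) plus four
#' harmonics at periods 365/k days, k = 1..4 (seasonal cycle), to the
#' retained records of a CO2 series. The fit is computed on a centred,
#' scaled time basis for numerical conditioning and the polynomial
#' coefficients are transformed back exactly to the days-from-first-record
#' basis.
#'
#' @param series a [co2_series()].
#' @return an object of class `co2_curvefit`: a list with
#'   \describe{
#'     \item{poly}{length-3 numeric, ppm / ppm day^-1 / ppm day^-2 on a
#'       time axis in days since the first retained record;}
#'     \item{harmonics}{4 x 2 matrix of sine/cosine coefficients (ppm),
#'       rows k = 1..4;}
#'     \item{residuals}{ppm at each retained record;}
#'     \item{t0}{absolute day index of the first retained record;}
#'     \item{t_retained}{absolute day indices of the retained records.}
#'   }
#'   The reconstruction identity `predict + residual == conc` holds at
#'   every retained record to 1e-9 ppm.
#' @export
fit_function <- function(series) {
  stopifnot(inherits(series, "co2_series"))
  ret <- retained(series)
  if (nrow(ret) < 12L) stop("too few retained records to fit")
  span <- max(ret$t) - min(ret$t)
  if (span < 3 * 365 - 7) stop("need at least 3 full years of retained data")

  t0 <- min(ret$t)
  td <- ret$t - t0                       # days since first retained record
  m <- span / 2
  ts <- (td - m) / m                     # centred, scaled to [-1, 1]
  H <- harmonic_basis(td)
  X <- cbind(1, ts, ts^2, H)
  fit <- stats::lm.fit(X, ret$conc)
  if (fit$rank < ncol(X)) stop("rank-deficient design: time axis degenerate")
  cf <- fit$coefficients
  # back-transform the quadratic from the ts basis to the td basis
  p0 <- cf[1L] - cf[2L] * m / m + cf[3L] * m^2 / m^2
  p1 <- cf[2L] / m - 2 * cf[3L] * m / m^2
  p2 <- cf[3L] / m^2
  harm <- matrix(cf[4:11], nrow = 4L, byrow = TRUE,
                 dimnames = list(paste0("k", 1:4), c("sin", "cos")))
  structure(list(poly = unname(c(p0, p1, p2)), harmonics = harm,
                 residuals = unname(fit$residuals), t0 = t0,
                 t_retained = ret$t,
                 poly_scaled = unname(cf[1:3]), scale_mid = m),
            class = "co2_curvefit")
}

harmonic_basis <- function(td) {
  out <- matrix(0, length(td), 8L)
  for (k in 1:4) {
    w <- 2 * pi * k * td / 365
    out[, 2L * k - 1L] <- sin(w)
    out[, 2L * k] <- cos(w)
  }
  out
}

#' Evaluate fitted components at arbitrary days
#'
#' @param fit a `co2_curvefit`.
#' @param t absolute day indices (same axis as the series the fit came
#'   from).
#' @param component `"full"`, `"poly"` or `"harmonics"`.
#' @return numeric vector of ppm.
#' @export
predict_fit <- function(fit, t, component = c("full", "poly", "harmonics")) {
  component <- match.arg(component)
  td <- t - fit$t0
  # evaluate the quadratic in the scaled basis it was fitted in, so the
  # fit + residual reconstruction identity holds to machine precision
  ts <- (td - fit$scale_mid) / fit$scale_mid
  p <- fit$poly_scaled[1L] + fit$poly_scaled[2L] * ts +
    fit$poly_scaled[3L] * ts^2
  h <- drop(harmonic_basis(td) %*% as.vector(t(fit$harmonics)))
  switch(component, full = p + h, poly = p, harmonics = h)
}

#' @export
print.co2_curvefit <- function(x, ...) {
  amp <- sqrt(rowSums(x$harmonics^2))
  cat(sprintf(
    "<co2_curvefit> poly = (%.3f, %.2e, %.2e); harmonic amps (ppm): %s\n",
    x$poly[1L], x$poly[2L], x$poly[3L],
    paste(sprintf("%.2f", amp), collapse = ", ")))
  invisible(x)
}

#' Iterative outlier rejection against the fitted function
#'
#' Records whose residual from the current fit exceeds `k` standard
#' deviations of the residuals are flagged `"outlier"`; the function is
#' refitted and the rule re-applied until no new rejections occur (at most
#' `max_iter` passes).
#'
#' @param series a [co2_series()].
#' @param k rejection threshold in residual standard deviations
#'   (default 5).
#' @param max_iter maximum fit/reject passes.
#' @return list with `series` (flags updated), `fit` (final
#'   `co2_curvefit` on the cleaned series) and `n_rejected`.
#' @export
reject_outliers <- function(series, k = 5, max_iter = 5L) {
  stopifnot(inherits(series, "co2_series"), k > 0)
  s <- series
  fit <- fit_function(s)
  n_total <- 0L
  for (iter in seq_len(max_iter)) {
    sd_res <- stats::sd(fit$residuals)
    if (!is.finite(sd_res) || sd_res < 1e-9) break  # exact fit: nothing to reject
    bad_t <- fit$t_retained[abs(fit$residuals) > k * sd_res]
    if (length(bad_t) == 0L) break
    s$flag[s$t %in% bad_t] <- "outlier"
    n_total <- n_total + length(bad_t)
    if (sum(s$flag == "retained") < 12L) stop("outlier rejection removed all data")
    fit <- fit_function(s)
  }
  list(series = s, fit = fit, n_rejected = n_total)
}

#' Gap-aware Gaussian smoothing filter specified by its FWHM
#'
#' Smooths a (possibly gappy) daily sequence with a Gaussian kernel of
#' standard deviation `fwhm_days / (2 sqrt(2 ln 2))`, truncated at +-3
#' sigma. Kernel weights are renormalised over the available (non-NA)
#' points, so gaps and series edges are handled without interpolation; a
#' day with no data anywhere within +-3 sigma is returned as `NA`.
#' The filter is linear in its input.
#'
#' @param x numeric vector on a uniform daily axis, `NA` where no data.
#' @param fwhm_days full width at half maximum of the kernel, days (> 0).
#' @return numeric vector, same length as `x`, defined on every day that
#'   has data within +-3 sigma.
#' @export
fwhm_filter <- function(x, fwhm_days) {
  stopifnot(is.numeric(x), fwhm_days > 0)
  sigma <- fwhm_days / (2 * sqrt(2 * log(2)))
  half <- as.integer(ceiling(3 * sigma))
  kern <- stats::dnorm(seq(-half, half), sd = sigma)
  ind <- as.numeric(!is.na(x))
  x0 <- ifelse(is.na(x), 0, x)
  pad <- numeric(half)
  num <- stats::filter(c(pad, x0, pad), kern, sides = 2)
  den <- stats::filter(c(pad, ind, pad), kern, sides = 2)
  num <- as.numeric(num)[(half + 1L):(half + length(x))]
  den <- as.numeric(den)[(half + 1L):(half + length(x))]
  out <- ifelse(den > 0, num / den, NA_real_)
  out
}

#' Decompose a CO2 record into trend and detrended seasonal curve
#'
#' The full decomposition chain: fit the quadratic + four-harmonic
#' function, reject outliers beyond `k` residual standard deviations
#' (daily records only; weekly records are taken as already screened),
#' then digitally filter the residuals with two gap-aware Gaussian FWHM
#' filters -- 45.66 days (1.5 months) to capture short-term variation S(t)
#' and 390 days for the long-term residual variation L(t). The components
#' are assembled on the full daily axis as
#' \deqn{trend(t) = poly(t) + L(t), \quad D(t) = harmonics(t) + S(t) - L(t)}
#' where D(t) is the detrended seasonal curve from which summer drawdown
#' and phenology dates are computed. Weekly input is fitted at its weekly
#' timestamps and the components evaluated on the daily axis.
#'
#' @param series a [co2_series()].
#' @param reject apply the outlier rule first? Defaults to `TRUE` for
#'   daily cadence, `FALSE` for weekly.
#' @param k outlier threshold in residual SD.
#' @param fwhm_short,fwhm_long filter widths in days.
#' @return object of class `co2_decomposition`: list with `axis` (data
#'   frame `year`, `doy`, `t`, `trend`, `seasonal`, `short`, `long`,
#'   `edge`), `fit`, `series` (cleaned), `n_outliers_removed`.
#' @export
decompose_co2 <- function(series, reject = NULL, k = 5,
                          fwhm_short = 45.66, fwhm_long = 390) {
  stopifnot(inherits(series, "co2_series"))
  cadence <- attr(series, "cadence")
  if (is.null(reject)) reject <- identical(cadence, "daily")
  n_out <- 0L
  if (reject) {
    rr <- reject_outliers(series, k = k)
    series <- rr$series
    fit <- rr$fit
    n_out <- rr$n_rejected
  } else {
    fit <- fit_function(series)
  }
  year0 <- series$year[1L]
  years <- seq.int(series$year[1L], series$year[nrow(series)])
  axis <- daily_axis(years)
  axis <- axis[axis$t >= min(series$t) & axis$t <= max(series$t), ,
               drop = FALSE]
  res <- rep(NA_real_, nrow(axis))
  res[match(fit$t_retained, axis$t)] <- fit$residuals
  S <- fwhm_filter(res, fwhm_short)
  L <- fwhm_filter(res, fwhm_long)
  trend <- predict_fit(fit, axis$t, "poly") + L
  D <- predict_fit(fit, axis$t, "harmonics") + (S - L)
  edge <- axis$t < min(series$t) + 182 | axis$t > max(series$t) - 182
  axis$trend <- trend
  axis$seasonal <- D
  axis$short <- S
  axis$long <- L
  axis$edge <- edge
  rownames(axis) <- NULL
  structure(list(axis = axis, fit = fit, series = series,
                 n_outliers_removed = n_out),
            class = "co2_decomposition")
}

#' @export
print.co2_decomposition <- function(x, ...) {
  cat(sprintf(
    "<co2_decomposition> %d days (%d-%d), %d outliers removed\n",
    nrow(x$axis), x$axis$year[1L], x$axis$year[nrow(x$axis)],
    x$n_outliers_removed))
  invisible(x)
}

#' Write a decomposition to CSV and its fit summary to JSON
#'
#' @param decomp a `co2_decomposition`.
#' @param csv_path,json_path output paths; either may be `NULL` to skip.
#' @return invisibly, a list of the paths written.
#' @export
write_decomposition <- function(decomp, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(decomp, "co2_decomposition"))
  if (!is.null(csv_path)) {
    ax <- decomp$axis
    conc <- rep(NA_real_, nrow(ax))
    flag <- rep("missing", nrow(ax))
    i <- match(decomp$series$t, ax$t)
    ok <- !is.na(i)
    conc[i[ok]] <- decomp$series$conc[ok]
    flag[i[ok]] <- decomp$series$flag[ok]
    out <- data.frame(year = ax$year, doy = ax$doy, conc = conc,
                      trend = ax$trend, detrended_seasonal = ax$seasonal,
                      flag = flag)
    utils::write.csv(out, csv_path, row.names = FALSE, na = "")
  }
  if (!is.null(json_path)) {
    fit <- decomp$fit
    jsonlite::write_json(
      list(poly = fit$poly,
           harmonics = list(sin = fit$harmonics[, "sin"],
                            cos = fit$harmonics[, "cos"]),
           harmonic_amplitude = sqrt(rowSums(fit$harmonics^2)),
           residual_sd = stats::sd(fit$residuals),
           n_retained = length(fit$residuals),
           n_outliers_removed = decomp$n_outliers_removed),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(list(csv = csv_path, json = json_path))
}
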