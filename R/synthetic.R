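# Synthetic world generator: a Barrow-like CO2 record whose summer
# drawdown is coupled, with a period-dependent coefficient, to the
# interannual summer temperature mode shared by a set of gridded climate
# fields. Every downstream stage of the pipeline can be tested against
# the ground truth this module records.

#' Parameters of the synthetic world
#'
#' Defaults encode the study conditions the analysis targets: a 34-year
#' record (1979-2012) split at 1996 into two 17-year periods, with the
#' drawdown-temperature coupling absent in the earlier period and
#' -2 ppm per degree C in the later one, superimposed on a quadratic
#' growth trend, a four-harmonic seasonal cycle with a late-August
#' trough, AR(1) synoptic noise, gaps and occasional spikes.
#'
#' @param years inclusive range of calendar years (>= 3 years).
#' @param base_conc mean concentration at the record start, ppm.
#' @param trend_lin,trend_quad growth-rate terms, ppm per year and ppm
#'   per year squared.
#' @param harmonic_amps 4 x 2 matrix of (amplitude ppm, phase rad) rows
#'   for harmonics k = 1..4 of the 365-day year.
#' @param coupling_early,coupling_late drawdown anomaly per degree of
#'   regional summer temperature anomaly, ppm per degree C, for years
#'   before / from `break_year`.
#' @param break_year first year of the later period.
#' @param t_anom_sd interannual SD of the regional summer temperature
#'   mode, degrees C.
#' @param drawdown_sigma SD of the white noise added to each year's
#'   imposed drawdown anomaly, ppm.
#' @param ar1_rho,ar1_sigma lag-1 autocorrelation (in \[0, 1)) and
#'   marginal SD (ppm) of the synoptic concentration noise.
#' @param gap_fraction fraction of days flagged missing (in \[0, 1)).
#' @param outlier_rate per-day probability of an injected spike.
#' @param outlier_scale spike magnitudes are `outlier_scale` times 5-20
#'   noise SDs.
#' @param grid list with `lat_min`, `lat_max`, `nlat`, `lon_min`,
#'   `lon_max`, `nlon` (cell centres are placed inside the extents).
#' @param field_noise_sd SD of the spatially correlated pixel noise on
#'   monthly temperature, degrees C.
#' @param daily_t_sd SD of day-to-day summer temperature noise, degrees
#'   C.
#' @param ndvi_beta_early,ndvi_beta_late NDVI response to the pixel
#'   summer temperature anomaly per period, NDVI per degree C.
#' @param heat_penalty NDVI lost per extreme warm day.
#' @param ndvi_noise_sd pixel NDVI noise SD.
#' @param hr_q10,hr_base,hr_t0 heterotrophic respiration response:
#'   `HR = hr_base * hr_q10^((T - hr_t0)/10) + noise`.
#' @param hr_noise_sd additive HR noise SD (same units as `hr_base`).
#' @param seed integer root seed; identical parameters and seed
#'   reproduce every output exactly.
#' @return validated parameter list of class `truth_params`.
#' @export
truth_params <- function(years = 1979:2012,
                         base_conc = 355,
                         trend_lin = 1.7,
                         trend_quad = 0.011,
                         harmonic_amps = default_harmonics(),
                         coupling_early = 0,
                         coupling_late = -2,
                         break_year = 1996L,
                         t_anom_sd = 0.8,
                         drawdown_sigma = 0.5,
                         ar1_rho = 0.7,
                         ar1_sigma = 1.0,
                         gap_fraction = 0.05,
                         outlier_rate = 0.002,
                         outlier_scale = 1,
                         grid = list(lat_min = 50, lat_max = 80, nlat = 20L,
                                     lon_min = 0, lon_max = 360, nlon = 40L),
                         field_noise_sd = 1.0,
                         daily_t_sd = 3.0,
                         ndvi_beta_early = 0.02,
                         ndvi_beta_late = 0,
                         heat_penalty = 0.002,
                         ndvi_noise_sd = 0.02,
                         hr_q10 = 2.0,
                         hr_base = 50,
                         hr_t0 = 10,
                         hr_noise_sd = 2,
                         seed = 1L) {
  p <- as.list(environment())
  p$years <- as.integer(p$years)
  if (length(p$years) < 3L) stop("degenerate year range: need >= 3 years")
  if (any(diff(p$years) != 1L)) stop("years must be consecutive")
  if (!(ar1_rho >= 0 && ar1_rho < 1)) stop("ar1_rho must be in [0, 1)")
  if (!(gap_fraction >= 0 && gap_fraction < 1)) {
    stop("gap_fraction must be in [0, 1)")
  }
  if (grid$lat_min < -90 || grid$lat_max > 90) {
    stop("grid latitudes must lie within [-90, 90]")
  }
  ha <- as.matrix(harmonic_amps)
  if (!identical(dim(ha), c(4L, 2L))) {
    stop("harmonic_amps must be a 4 x 2 (amplitude, phase) matrix")
  }
  p$harmonic_amps <- ha
  p$seed <- as.integer(seed)
  structure(p, class = "truth_params")
}

#' Default seasonal harmonics of the synthetic record
#'
#' Amplitude/phase pairs projecting a Barrow-like seasonal cycle
#' (spring maximum, steep July decline, late-August trough, winter
#' plateau) onto four harmonics; the resulting curve crosses zero
#' downward near day 176 and bottoms out near day 225 with a
#' climatological July-August drawdown of about 6 ppm.
#'
#' @return 4 x 2 matrix, columns `amp` (ppm) and `phase` (radians).
#' @export
default_harmonics <- function() {
  matrix(c(5.9848, 0.3395,
           3.5068, 3.1059,
           1.1707, 0.0302,
           0.4032, -2.6845),
         nrow = 4L, byrow = TRUE,
         dimnames = list(paste0("k", 1:4), c("amp", "phase")))
}

# deterministic sub-seeds per component, derived from the root seed
sub_seeds <- function(params) {
  withr_seed(params$seed, sample.int(.Machine$integer.max - 1L, 14L))
}

seasonal_curve <- function(doy, harmonic_amps) {
  out <- numeric(length(doy))
  for (k in 1:4) {
    out <- out + harmonic_amps[k, 1L] *
      sin(2 * pi * k * doy / 365 + harmonic_amps[k, 2L])
  }
  out
}

# weight of the July-August descending limb: 0 before 1 July, smoothly
# down to -1 by 25 August, held through the measurement window, relaxed
# back to 0 by year end (continuous across the year boundary)
limb_weight <- function(doy) {
  w <- numeric(length(doy))
  ramp <- doy >= 182 & doy < 237
  w[ramp] <- -(1 - cos(pi * (doy[ramp] - 182) / 55)) / 2
  hold <- doy >= 237 & doy < 280
  w[hold] <- -1
  rec <- doy >= 280
  w[rec] <- -(1 + cos(pi * (doy[rec] - 280) / 85)) / 2
  w
}

#' The regional summer temperature anomaly mode
#'
#' The interannual mode shared between the CO2 generator (which couples
#' the drawdown to it) and the climate-field generator (whose regional
#' summer mean equals it by construction). Deterministic in the root
#' seed.
#'
#' @param params a [truth_params()].
#' @return numeric vector, one anomaly (degrees C) per year.
#' @export
truth_t_anom <- function(params) {
  ss <- sub_seeds(params)
  withr_seed(ss[1L], stats::rnorm(length(params$years), 0, params$t_anom_sd))
}

year_coupling <- function(params) {
  ifelse(params$years < params$break_year,
         params$coupling_early, params$coupling_late)
}

#' Generate the synthetic CO2 record with its ground truth
#'
#' Daily concentrations assembled as quadratic trend + harmonic seasonal
#' cycle + per-year drawdown perturbation + AR(1) synoptic noise, with
#' random gaps and injected outlier spikes. The per-year drawdown
#' anomaly is `coupling(period) * T_anom(year) + N(0, drawdown_sigma)`,
#' applied by scaling the July-August descending limb of the seasonal
#' function; the truth record stores the temperature anomalies and
#' imposed drawdown anomalies for downstream recovery tests.
#'
#' @param params a [truth_params()].
#' @return object of class `co2_sim`: list with `series` (a
#'   [co2_series()]) and `truth` (list: `years`, `t_anom`,
#'   `drawdown_anom`, `coupling`, `outlier_t`, `gap_t`, `params`).
#' @export
generate_co2_series <- function(params) {
  stopifnot(inherits(params, "truth_params"))
  ss <- sub_seeds(params)
  years <- params$years
  ax <- daily_axis(years)
  n <- nrow(ax)
  yr_frac <- ax$t / 365

  t_anom <- truth_t_anom(params)
  coup <- year_coupling(params)
  d_anom <- coup * t_anom +
    withr_seed(ss[2L], stats::rnorm(length(years), 0, params$drawdown_sigma))

  conc <- params$base_conc + params$trend_lin * yr_frac +
    params$trend_quad * yr_frac^2 +
    seasonal_curve(ax$doy, params$harmonic_amps) +
    d_anom[match(ax$year, years)] * limb_weight(ax$doy)

  if (params$ar1_sigma > 0) {
    noise <- withr_seed(ss[3L], {
      innov <- stats::rnorm(n, 0, params$ar1_sigma *
                              sqrt(1 - params$ar1_rho^2))
      e <- as.numeric(stats::filter(innov, params$ar1_rho,
                                    method = "recursive",
                                    init = stats::rnorm(1, 0,
                                                        params$ar1_sigma)))
      e
    })
    conc <- conc + noise
  }

  flag <- rep("retained", n)
  if (params$gap_fraction > 0) {
    gap <- withr_seed(ss[4L], stats::runif(n) < params$gap_fraction)
    flag[gap] <- "missing"
  }
  outlier_t <- integer(0)
  if (params$outlier_rate > 0) {
    spikes <- withr_seed(ss[5L], {
      hit <- stats::runif(n) < params$outlier_rate
      hit <- hit & flag == "retained"
      mag <- stats::runif(sum(hit), 5, 20) *
        max(params$ar1_sigma, 1) * params$outlier_scale
      sgn <- sample(c(-1, 1), sum(hit), replace = TRUE)
      list(hit = hit, delta = mag * sgn)
    })
    conc[spikes$hit] <- conc[spikes$hit] + spikes$delta
    outlier_t <- ax$t[spikes$hit]
  }
  conc[flag == "missing"] <- NA_real_
  series <- co2_series(ax$year, ax$doy, conc, flag, cadence = "daily")
  truth <- list(years = years, t_anom = t_anom, drawdown_anom = d_anom,
                coupling = coup, outlier_t = outlier_t,
                gap_t = ax$t[flag == "missing"], params = params)
  structure(list(series = series, truth = truth), class = "co2_sim")
}

#' @export
print.co2_sim <- function(x, ...) {
  cat(sprintf(
    "<co2_sim> %d years, %d spikes, %d gaps; coupling %.2f -> %.2f ppm/degC\n",
    length(x$truth$years), length(x$truth$outlier_t),
    length(x$truth$gap_t), x$truth$params$coupling_early,
    x$truth$params$coupling_late))
  invisible(x)
}

grid_axes <- function(grid) {
  dlat <- (grid$lat_max - grid$lat_min) / grid$nlat
  dlon <- (grid$lon_max - grid$lon_min) / grid$nlon
  list(lat = grid$lat_min + dlat * (seq_len(grid$nlat) - 0.5),
       lon = grid$lon_min + dlon * (seq_len(grid$nlon) - 0.5))
}

# smoothing matrix whose rows have unit sum of squares, so smoothing a
# white unit-variance field preserves the marginal variance while
# imposing spatial correlation
smoother <- function(n, scale) {
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  k <- exp(-d^2 / (2 * scale^2))
  k / sqrt(rowSums(k^2))
}

correlated_noise <- function(nlat, nlon, sd, k_lat, k_lon) {
  if (sd == 0) return(matrix(0, nlat, nlon))
  sd * (k_lat %*% matrix(stats::rnorm(nlat * nlon), nlat, nlon) %*%
          t(k_lon))
}

monthly_t_clim <- function(lat, month) {
  outer(8 - 0.5 * (lat - 50), 15 * cos(2 * pi * (month - 7) / 12), "+")
}

#' Generate the gridded climate fields
#'
#' Monthly temperature, precipitation and cloud cover on the parameter
#' grid, plus daily July-August temperature. The July and August
#' temperature anomalies share the regional interannual mode
#' [truth_t_anom()]: spatially correlated pixel noise is added and then
#' re-centred so that the cosine-latitude regional summer mean equals
#' the mode exactly (plus the constant climatology). Precipitation and
#' cloudiness carry their own interannual modes, partially correlated
#' with temperature. Daily summer temperature is the pixel summer state
#' plus independent day-to-day noise of SD `daily_t_sd`.
#'
#' @param params a [truth_params()].
#' @param include_daily generate the daily July-August temperature field
#'   (the largest output; only needed for extreme-day and
#'   temperature-variability analyses)?
#' @return list with monthly [grid_field()]s `temperature` (degC),
#'   `precipitation` (mm), `cloud` (%), a daily `daily_temperature`
#'   (degC, July-August only; `NULL` when `include_daily = FALSE`), and
#'   `t_anom`, the shared mode.
#' @export
generate_climate_fields <- function(params, include_daily = TRUE) {
  stopifnot(inherits(params, "truth_params"))
  ss <- sub_seeds(params)
  axes <- grid_axes(params$grid)
  lat <- axes$lat; lon <- axes$lon
  nlat <- length(lat); nlon <- length(lon)
  years <- params$years
  ny <- length(years)
  t_anom <- truth_t_anom(params)
  k_lat <- smoother(nlat, 2)
  k_lon <- smoother(nlon, 3)
  coslat_mean <- function(m) {
    w <- matrix(cos(lat * pi / 180), nlat, nlon)
    sum(w * m) / sum(w)
  }

  tm <- data.frame(year = rep(years, each = 12L),
                   month = rep.int(1:12, ny))
  tclim <- monthly_t_clim(lat, 1:12)  # nlat x 12

  temp <- withr_seed(ss[6L], {
    v <- array(0, c(nlat, nlon, nrow(tm)))
    for (i in seq_len(nrow(tm))) {
      mo <- tm$month[i]
      base <- matrix(tclim[, mo], nlat, nlon)
      nz <- correlated_noise(nlat, nlon, params$field_noise_sd, k_lat, k_lon)
      if (mo %in% c(7L, 8L)) {
        nz <- nz - coslat_mean(nz)      # regional mean is the mode, exactly
        base <- base + t_anom[match(tm$year[i], years)]
      }
      v[, , i] <- base + nz
    }
    v
  })

  p_mode <- withr_seed(ss[7L], {
    8 * (0.3 * t_anom / params$t_anom_sd +
           sqrt(1 - 0.3^2) * stats::rnorm(ny))
  })
  precip <- withr_seed(ss[8L], {
    v <- array(0, c(nlat, nlon, nrow(tm)))
    for (i in seq_len(nrow(tm))) {
      base <- 60 + 20 * cos(2 * pi * (tm$month[i] - 8) / 12)
      a <- if (tm$month[i] %in% c(7L, 8L)) {
        p_mode[match(tm$year[i], years)]
      } else 0
      v[, , i] <- pmax(base + a +
                         correlated_noise(nlat, nlon, 10, k_lat, k_lon), 0)
    }
    v
  })

  c_mode <- withr_seed(ss[9L], {
    3 * (-0.4 * t_anom / params$t_anom_sd +
           sqrt(1 - 0.4^2) * stats::rnorm(ny))
  })
  cloud <- withr_seed(ss[10L], {
    v <- array(0, c(nlat, nlon, nrow(tm)))
    for (i in seq_len(nrow(tm))) {
      a <- if (tm$month[i] %in% c(7L, 8L)) {
        c_mode[match(tm$year[i], years)]
      } else 0
      v[, , i] <- pmin(pmax(65 + a +
                              correlated_noise(nlat, nlon, 5, k_lat, k_lon),
                            0), 100)
    }
    v
  })

  nd <- length(.DOY_SUMMER)
  dtm <- data.frame(year = rep(years, each = nd),
                    doy = rep.int(.DOY_SUMMER, ny))
  daily <- if (!include_daily) NULL else withr_seed(ss[11L], {
    v <- array(stats::rnorm(nlat * nlon * nd * ny, 0, params$daily_t_sd),
               c(nlat, nlon, nd * ny))
    clim_d <- outer(8 - 0.5 * (lat - 50),
                    15 * cos(2 * pi * (.DOY_SUMMER - 196) / 365), "+")
    clim_arr <- aperm(array(clim_d, c(nlat, nd, nlon)), c(1L, 3L, 2L))
    v <- v + as.vector(clim_arr)    # recycled over years blockwise
    for (j in seq_len(ny)) {
      pix <- t_anom[j] +
        correlated_noise(nlat, nlon, params$field_noise_sd, k_lat, k_lon)
      idx <- (j - 1L) * nd + seq_len(nd)
      v[, , idx] <- v[, , idx] + as.vector(pix)
    }
    v
  })

  list(
    temperature = grid_field(lat, lon, tm, temp, "degC", "temperature"),
    precipitation = grid_field(lat, lon, tm, precip, "mm", "precipitation"),
    cloud = grid_field(lat, lon, tm, cloud, "%", "cloud"),
    daily_temperature = if (is.null(daily)) NULL else {
      grid_field(lat, lon, dtm, daily, "degC", "daily_temperature")
    },
    t_anom = t_anom
  )
}

#' Generate summer NDVI coupled to temperature
#'
#' Annual summer NDVI per pixel: a latitude-dependent climatology plus a
#' period-dependent linear response to the pixel's summer temperature
#' anomaly, minus an optional heat-stress penalty proportional to the
#' extreme-warm-day count, plus noise, clipped to \[-0.1, 1\]. The
#' climatology declines poleward and falls below the 0.1 vegetated-land
#' threshold at the highest latitudes, so the mask is non-trivial.
#'
#' @param params a [truth_params()].
#' @param t_field the monthly temperature [grid_field()] from
#'   [generate_climate_fields()].
#' @param daily_t optional daily temperature field; when supplied, the
#'   heat-stress penalty `heat_penalty * extreme_day_count` (90th
#'   percentile over all years) is active.
#' @return list with `ndvi` (annual [grid_field()], units `"1"`),
#'   `climatology` (single-slice [grid_field()]) and `beta`, the per-year
#'   response used.
#' @export
generate_ndvi <- function(params, t_field, daily_t = NULL) {
  stopifnot(inherits(params, "truth_params"),
            inherits(t_field, "grid_field"))
  ss <- sub_seeds(params)
  years <- sort(unique(t_field$time$year))
  nlat <- length(t_field$lat); nlon <- length(t_field$lon)
  summer <- vapply(years, function(y) summer_mean(t_field, y, fun = "mean"),
                   matrix(0, nlat, nlon))
  pix_clim <- apply(summer, c(1L, 2L), mean)
  beta <- ifelse(years < params$break_year,
                 params$ndvi_beta_early, params$ndvi_beta_late)
  clim <- matrix(0.7 - 0.022 * (t_field$lat - 50), nlat, nlon)
  counts <- NULL
  if (!is.null(daily_t) && params$heat_penalty != 0) {
    stop_grid_mismatch(t_field, daily_t)
    counts <- extreme_day_counts(daily_t, base_years = years,
                                 eval_years = years)
  }
  vals <- withr_seed(ss[12L], {
    v <- array(0, c(nlat, nlon, length(years)))
    for (j in seq_along(years)) {
      x <- clim + beta[j] * (summer[, , j] - pix_clim)
      if (!is.null(counts)) x <- x - params$heat_penalty * counts[, , j]
      if (params$ndvi_noise_sd > 0) {
        x <- x + matrix(stats::rnorm(nlat * nlon, 0, params$ndvi_noise_sd),
                        nlat, nlon)
      }
      v[, , j] <- pmin(pmax(x, -0.1), 1)
    }
    v
  })
  tm <- data.frame(year = years)
  list(ndvi = grid_field(t_field$lat, t_field$lon, tm, vals, "1", "ndvi"),
       climatology = grid_field(t_field$lat, t_field$lon, NULL,
                                apply(vals, c(1L, 2L), mean), "1",
                                "ndvi_climatology"),
       beta = beta)
}

#' Generate summer heterotrophic respiration
#'
#' `HR = hr_base * hr_q10^((T - hr_t0) / 10) + noise`, strictly
#' positive: the standard exponential temperature response, so HR is
#' positively coupled to summer temperature in both periods.
#'
#' @param params a [truth_params()].
#' @param t_field monthly temperature [grid_field()].
#' @return annual [grid_field()] of summer HR.
#' @export
generate_hr <- function(params, t_field) {
  stopifnot(inherits(params, "truth_params"),
            inherits(t_field, "grid_field"))
  ss <- sub_seeds(params)
  years <- sort(unique(t_field$time$year))
  nlat <- length(t_field$lat); nlon <- length(t_field$lon)
  vals <- withr_seed(ss[13L], {
    v <- array(0, c(nlat, nlon, length(years)))
    for (j in seq_along(years)) {
      tg <- summer_mean(t_field, years[j], fun = "mean")
      x <- params$hr_base * params$hr_q10^((tg - params$hr_t0) / 10)
      if (params$hr_noise_sd > 0) {
        x <- x + matrix(stats::rnorm(nlat * nlon, 0, params$hr_noise_sd),
                        nlat, nlon)
      }
      v[, , j] <- pmax(x, 1e-6)
    }
    v
  })
  grid_field(t_field$lat, t_field$lon, data.frame(year = years), vals,
             "gC m-2", "hr")
}

#' Generate a station footprint sensitivity grid
#'
#' A smooth, non-negative surface-sensitivity field: two Gaussian bumps
#' (an Alaska/Chukchi centre near the station and a secondary Siberian
#' lobe, with longitude wrap-around), max-normalised to 1. Deterministic
#' in the parameters; stands in for a transport-model sensitivity map,
#' which is consumed, never simulated physically.
#'
#' @param params a [truth_params()].
#' @return single-slice [grid_field()], units `"s"`.
#' @export
generate_footprint <- function(params) {
  stopifnot(inherits(params, "truth_params"))
  axes <- grid_axes(params$grid)
  lat <- axes$lat; lon <- axes$lon
  wrap <- function(d) pmin(abs(d), 360 - abs(d))
  bump <- function(lat0, lon0, slat, slon, h) {
    dl <- outer((lat - lat0)^2 / (2 * slat^2),
                wrap(lon - lon0)^2 / (2 * slon^2), "+")
    h * exp(-dl)
  }
  f <- bump(68, 200, 6, 35, 1) + bump(64, 140, 7, 30, 0.5)
  f <- f / max(f)
  grid_field(lat, lon, NULL, f, "s", "footprint")
}

#' Generate every input of the pipeline at once
#'
#' @param params a [truth_params()].
#' @return list with `params`, `co2` (a `co2_sim`), `climate` (see
#'   [generate_climate_fields()]), `ndvi`, `hr`, `footprint`, `mask`
#'   (vegetated-land matrix) and `truth` (the CO2 truth record).
#' @export
simulate_world <- function(params = truth_params()) {
  co2 <- generate_co2_series(params)
  climate <- generate_climate_fields(params)
  ndvi <- generate_ndvi(params, climate$temperature,
                        daily_t = climate$daily_temperature)
  hr <- generate_hr(params, climate$temperature)
  footprint <- generate_footprint(params)
  mask <- vegetated_mask(ndvi$climatology)
  list(params = params, co2 = co2, climate = climate, ndvi = ndvi,
       hr = hr, footprint = footprint, mask = mask, truth = co2$truth)
}

#' Write the truth record as JSON
#'
#' @param truth the `truth` element of a `co2_sim`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(
    list(years = truth$years, t_anom = truth$t_anom,
         drawdown_anom = truth$drawdown_anom, coupling = truth$coupling,
         outlier_t = truth$outlier_t, gap_t = truth$gap_t,
         seed = truth$params$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
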