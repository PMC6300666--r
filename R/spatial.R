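# Regional aggregation of gridded fields: everything the statistics
# consume is a per-year scalar built here from masked cosine-latitude or
# footprint-weighted means over vegetated land north of 50 degrees N.

#' Vegetated-land mask from an NDVI climatology
#'
#' @param ndvi_clim a [grid_field()] holding the long-term mean annual
#'   NDVI (single time slice), or a matrix.
#' @param threshold mask is `TRUE` where NDVI is strictly above this
#'   value (default 0.1).
#' @return logical matrix `(nlat, nlon)`.
#' @export
vegetated_mask <- function(ndvi_clim, threshold = 0.1) {
  v <- if (inherits(ndvi_clim, "grid_field")) {
    if (dim(ndvi_clim$values)[3L] != 1L) {
      stop("ndvi_clim must be a time-mean (single slice); average first")
    }
    ndvi_clim$values[, , 1L]
  } else {
    as.matrix(ndvi_clim)
  }
  v > threshold
}

#' July-August composite of a monthly field
#'
#' Per-pixel summer value for one year: the July/August mean for state
#' variables, or the July + August total when `fun = "sum"` (the
#' climatological convention for precipitation; chosen automatically for
#' fields in mm).
#'
#' @param field a monthly [grid_field()].
#' @param year calendar year.
#' @param fun `"mean"`, `"sum"` or `"auto"` (sum iff units are `"mm"`).
#' @return numeric matrix `(nlat, nlon)`.
#' @export
summer_mean <- function(field, year, fun = c("auto", "mean", "sum")) {
  fun <- match.arg(fun)
  stopifnot(inherits(field, "grid_field"))
  if (fun == "auto") fun <- if (identical(field$units, "mm")) "sum" else "mean"
  i7 <- slice_index(field, year, month = 7L)
  i8 <- slice_index(field, year, month = 8L)
  if (length(i7) != 1L || length(i8) != 1L) {
    stop("year ", year, ": July/August slice missing")
  }
  a <- field$values[, , i7] + field$values[, , i8]
  if (fun == "mean") a / 2 else a
}

#' Cosine-latitude weighted regional mean
#'
#' @param grid numeric matrix `(nlat, nlon)`.
#' @param lat grid-cell latitudes (degrees), length `nlat`.
#' @param mask logical matrix of pixels to include (default: all).
#' @param lat_min southern cut-off in degrees (default 50).
#' @return scalar weighted mean.
#' @export
regional_mean <- function(grid, lat, mask = NULL, lat_min = 50) {
  grid <- as.matrix(grid)
  if (is.null(mask)) mask <- array(TRUE, dim(grid))
  w <- matrix(cos(lat * pi / 180), nrow(grid), ncol(grid))
  w[!mask | matrix(lat, nrow(grid), ncol(grid)) < lat_min | is.na(grid)] <- 0
  if (sum(w) <= 0) stop("no pixels selected for the regional mean")
  sum(w * grid) / sum(w)
}

#' Footprint-weighted regional mean
#'
#' Weights each pixel by the station's (non-negative) surface sensitivity
#' times the cosine of latitude, over the masked pixels; no sensitivity
#' cut-off is applied, so weakly sensitive pixels contribute in
#' proportion to their sensitivity.
#'
#' @param grid numeric matrix `(nlat, nlon)`.
#' @param footprint a [grid_field()] (single slice) or matrix of
#'   sensitivities, same grid shape.
#' @param lat grid-cell latitudes, length `nlat`.
#' @param mask logical matrix (default: all pixels).
#' @return scalar weighted mean.
#' @export
footprint_weighted_mean <- function(grid, footprint, lat, mask = NULL) {
  grid <- as.matrix(grid)
  fp <- if (inherits(footprint, "grid_field")) footprint$values[, , 1L]
        else as.matrix(footprint)
  if (!identical(dim(fp), dim(grid))) stop("footprint grid mismatch")
  if (any(fp < 0, na.rm = TRUE)) stop("footprint sensitivities must be >= 0")
  if (is.null(mask)) mask <- array(TRUE, dim(grid))
  w <- fp * matrix(cos(lat * pi / 180), nrow(grid), ncol(grid))
  w[!mask | is.na(grid)] <- 0
  if (sum(w) <= 0) stop("all footprint weights are zero over the mask")
  sum(w * grid) / sum(w)
}

#' Per-year regional scalar series from a monthly field
#'
#' Summer (July-August) composites aggregated to one value per year under
#' the chosen weighting; the tidy per-year series all statistics consume.
#'
#' @param field a monthly [grid_field()].
#' @param years calendar years.
#' @param mask logical vegetated-land matrix.
#' @param weighting `"coslat"` (cosine-latitude mean north of `lat_min`)
#'   or `"footprint"`.
#' @param footprint sensitivity grid, required for footprint weighting.
#' @param lat_min southern cut-off for `"coslat"`.
#' @param fun summer composite rule, see [summer_mean()].
#' @return data frame `year`, `value`, `variable`, `weighting`.
#' @export
regional_series <- function(field, years, mask = NULL,
                            weighting = c("coslat", "footprint"),
                            footprint = NULL, lat_min = 50, fun = "auto") {
  weighting <- match.arg(weighting)
  vals <- vapply(years, function(y) {
    g <- summer_mean(field, y, fun = fun)
    if (weighting == "coslat") {
      regional_mean(g, field$lat, mask, lat_min = lat_min)
    } else {
      if (is.null(footprint)) stop("footprint weighting needs a footprint")
      footprint_weighted_mean(g, footprint, field$lat, mask)
    }
  }, numeric(1L))
  data.frame(year = years, value = vals, variable = field$name,
             weighting = if (weighting == "coslat") "coslat-north50"
                         else "footprint")
}

#' Extreme-warm-day counts against a base-period percentile
#'
#' Per pixel, the threshold is the empirical `pctl`-th percentile
#' (linear interpolation between order statistics) of all July-August
#' daily temperatures pooled over the base years; the count is the number
#' of July-August days in the evaluation year strictly above it.
#'
#' @param daily_t a daily [grid_field()] covering July-August of the base
#'   and evaluation years.
#' @param base_years years defining the percentile (>= 5).
#' @param eval_year year whose days are counted.
#' @param pctl percentile, default 90.
#' @return integer matrix `(nlat, nlon)` of counts.
#' @export
extreme_warm_days <- function(daily_t, base_years, eval_year, pctl = 90) {
  extreme_day_counts(daily_t, base_years, eval_year, pctl)[, , 1L]
}

# vectorised over evaluation years: the base-period threshold is
# computed once and reused
extreme_day_counts <- function(daily_t, base_years, eval_years, pctl = 90) {
  stopifnot(inherits(daily_t, "grid_field"))
  if (length(base_years) < 5L) stop("base period must cover at least 5 years")
  ib <- unlist(lapply(base_years, function(y) {
    slice_index(daily_t, y, doy = .DOY_SUMMER)
  }))
  base <- daily_t$values[, , ib, drop = FALSE]
  thr <- apply(base, c(1L, 2L), stats::quantile, probs = pctl / 100,
               names = FALSE, type = 7)
  nlat <- dim(base)[1L]; nlon <- dim(base)[2L]
  out <- array(0L, c(nlat, nlon, length(eval_years)))
  for (j in seq_along(eval_years)) {
    ie <- slice_index(daily_t, eval_years[j], doy = .DOY_SUMMER)
    if (length(ie) == 0L) {
      stop("no July-August days for year ", eval_years[j])
    }
    ev <- daily_t$values[, , ie, drop = FALSE]
    cnt <- rowSums(sweep(ev, c(1L, 2L), thr, ">"), dims = 2L)
    storage.mode(cnt) <- "integer"
    out[, , j] <- cnt
  }
  out
}

#' Within-summer daily temperature variability
#'
#' Sample standard deviation of July-August daily temperature per pixel
#' and year (pixels with fewer than `min_days` of the 62 days present are
#' set missing), its cosine-latitude regional series, and the linear
#' trend test on that series -- the diagnostic that the temperature
#' variance is stable across the record.
#'
#' @param daily_t a daily [grid_field()].
#' @param years calendar years.
#' @param mask optional vegetated-land matrix for the regional series.
#' @param min_days minimum July-August days required per pixel-year.
#' @param lat_min southern cut-off for the regional mean.
#' @return list with `sd_grid` (array `(nlat, nlon, nyear)`), `regional`
#'   (data frame `year`, `value`), and `trend` (list `slope`, `se`,
#'   `p` from the OLS trend of the regional SD on year).
#' @export
temp_variability <- function(daily_t, years, mask = NULL, min_days = 50L,
                             lat_min = 50) {
  stopifnot(inherits(daily_t, "grid_field"))
  nlat <- length(daily_t$lat); nlon <- length(daily_t$lon)
  sd_grid <- array(NA_real_, c(nlat, nlon, length(years)))
  for (j in seq_along(years)) {
    i <- slice_index(daily_t, years[j], doy = .DOY_SUMMER)
    block <- daily_t$values[, , i, drop = FALSE]
    n_ok <- apply(!is.na(block), c(1L, 2L), sum)
    s <- apply(block, c(1L, 2L), stats::sd, na.rm = TRUE)
    s[n_ok < min_days] <- NA_real_
    sd_grid[, , j] <- s
  }
  reg <- vapply(seq_along(years), function(j) {
    regional_mean(sd_grid[, , j], daily_t$lat, mask, lat_min = lat_min)
  }, numeric(1L))
  regional <- data.frame(year = years, value = reg)
  trend <- if (length(years) >= 5L) date_trend(years, reg) else NULL
  list(sd_grid = sd_grid, regional = regional, trend = trend)
}
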