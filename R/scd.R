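# Summer CO2 drawdown and phenology dates from the detrended seasonal
# curve D(t). Sign convention throughout: SCD = early-summer minus
# late-summer concentration, so positive SCD means CO2 declined (carbon
# was taken up) and a warm year with less uptake shows a *lower* SCD.

# D(t) for one year as a function of (possibly fractional) day-of-year
year_curve <- function(decomp, year) {
  ax <- decomp$axis
  ax[ax$year == year, c("doy", "seasonal")]
}

d_at <- function(doy_grid, d_vals, doy) {
  if (doy < min(doy_grid) || doy > max(doy_grid)) {
    stop("day ", doy, " outside the available curve")
  }
  stats::approx(doy_grid, d_vals, xout = doy, rule = 1)$y
}

#' Summer drawdown over the fixed July / August windows
#'
#' The primary drawdown definition: mean of the detrended seasonal curve
#' over July 1-7 minus its mean over August 25-31 of the given year.
#'
#' @param decomp a [decompose_co2()] result.
#' @param year calendar year, fully covered by the decomposition.
#' @return one-row data frame (an SCD record): `year`, `scd` (ppm),
#'   `method`, `window_start`, `window_end` (day-of-year).
#' @export
scd_fixed_window <- function(decomp, year) {
  stopifnot(inherits(decomp, "co2_decomposition"))
  yc <- year_curve(decomp, year)
  w1 <- yc$seasonal[match(.DOY_JUL1:.DOY_JUL7, yc$doy)]
  w2 <- yc$seasonal[match(.DOY_AUG25:.DOY_AUG31, yc$doy)]
  miss <- c((.DOY_JUL1:.DOY_JUL7)[is.na(w1)], (.DOY_AUG25:.DOY_AUG31)[is.na(w2)])
  if (length(miss)) {
    stop("year ", year, ": seasonal curve missing on day(s) ",
         paste(miss, collapse = ", "))
  }
  data.frame(year = year, scd = mean(w1) - mean(w2), method = "fixed-window",
             window_start = .DOY_JUL1, window_end = .DOY_AUG31)
}

#' Spring zero-crossing and trough dates of the seasonal curve
#'
#' The spring zero-crossing is the (fractional, linearly interpolated)
#' day-of-year where D(t) crosses zero downward within days 100-300; when
#' several downward crossings exist the one nearest day 178 (the
#' climatological crossing at Barrow) is taken. The trough is the day of
#' minimum D within days 150-300, earliest day on ties. With
#' `year = NULL` the dates are computed on the multi-year mean
#' (climatological) curve over `years`.
#'
#' @param decomp a [decompose_co2()] result.
#' @param year a single year, or `NULL` for the climatology.
#' @param years years entering the climatological mean curve (default:
#'   all fully covered years).
#' @return one-row data frame: `label`, `zero_crossing_doy`,
#'   `trough_doy`.
#' @export
pheno_dates <- function(decomp, year = NULL, years = NULL) {
  stopifnot(inherits(decomp, "co2_decomposition"))
  ax <- decomp$axis
  if (is.null(year)) {
    if (is.null(years)) {
      cov <- table(ax$year[!is.na(ax$seasonal)])
      years <- as.integer(names(cov))[cov == 365L]
    }
    sub <- ax[ax$year %in% years, ]
    d <- tapply(sub$seasonal, sub$doy, mean, na.rm = TRUE)
    doy_grid <- as.integer(names(d))
    d <- as.numeric(d)
    label <- "climatology"
  } else {
    yc <- year_curve(decomp, year)
    doy_grid <- yc$doy
    d <- yc$seasonal
    label <- as.character(year)
  }
  in_range <- doy_grid >= 100L & doy_grid <= 300L
  if (any(is.na(d[in_range]))) {
    stop(label, ": seasonal curve undefined within the search range")
  }
  # downward zero crossings within DOY 100..300
  i_all <- which(doy_grid >= 100L & doy_grid < 300L)
  i_all <- i_all[i_all < length(d)]
  cross <- i_all[d[i_all] > 0 & d[i_all + 1L] <= 0]
  if (length(cross) == 0L) {
    stop(label, ": no downward zero crossing in days 100-300")
  }
  frac <- doy_grid[cross] + d[cross] / (d[cross] - d[cross + 1L])
  zc <- frac[which.min(abs(frac - 178))]
  tr_range <- which(doy_grid >= 150L & doy_grid <= 300L)
  trough <- doy_grid[tr_range[which.min(d[tr_range])]]
  if (trough <= zc) {
    stop(label, ": trough date does not follow the zero crossing")
  }
  data.frame(label = label, zero_crossing_doy = zc,
             trough_doy = as.numeric(trough))
}

#' Drawdown between two days of the year
#'
#' D(year, d1) - D(year, d2) with the curve evaluated at fractional days
#' by linear interpolation; used for the climatological-dates and
#' annual-dates drawdown variants.
#'
#' @param decomp a [decompose_co2()] result.
#' @param year calendar year.
#' @param d1,d2 day-of-year bounds, `d1 < d2`.
#' @param method label recorded on the result.
#' @return one-row SCD record as in [scd_fixed_window()].
#' @export
scd_between_dates <- function(decomp, year, d1, d2,
                              method = "climatological-dates") {
  stopifnot(inherits(decomp, "co2_decomposition"))
  if (!(d1 < d2)) stop("degenerate window: d1 must be < d2")
  yc <- year_curve(decomp, year)
  ok <- !is.na(yc$seasonal)
  v1 <- d_at(yc$doy[ok], yc$seasonal[ok], d1)
  v2 <- d_at(yc$doy[ok], yc$seasonal[ok], d2)
  if (is.na(v1) || is.na(v2)) {
    stop("year ", year, ": seasonal curve missing inside the window")
  }
  data.frame(year = year, scd = v1 - v2, method = method,
             window_start = d1, window_end = d2)
}

#' Per-year drawdown series under a named definition
#'
#' @param decomp a [decompose_co2()] result.
#' @param years years to evaluate.
#' @param method `"fixed-window"` (July 1-7 vs August 25-31),
#'   `"climatological-dates"` (between the climatological zero-crossing
#'   and trough dates) or `"annual-dates"` (between each year's own
#'   dates).
#' @param clim_years years defining the climatological dates (default
#'   `years`).
#' @return data frame of SCD records, one row per year.
#' @export
scd_series <- function(decomp, years,
                       method = c("fixed-window", "climatological-dates",
                                  "annual-dates"),
                       clim_years = years) {
  method <- match.arg(method)
  if (method == "fixed-window") {
    out <- lapply(years, function(y) scd_fixed_window(decomp, y))
  } else if (method == "climatological-dates") {
    pd <- pheno_dates(decomp, years = clim_years)
    out <- lapply(years, function(y) {
      scd_between_dates(decomp, y, pd$zero_crossing_doy, pd$trough_doy,
                        method = method)
    })
  } else {
    out <- lapply(years, function(y) {
      pd <- pheno_dates(decomp, year = y)
      scd_between_dates(decomp, y, pd$zero_crossing_doy, pd$trough_doy,
                        method = method)
    })
  }
  do.call(rbind, out)
}

#' Linear trend in a phenology-date series
#'
#' Ordinary least-squares slope of day-of-year on calendar year with its
#' two-sided t-test p-value; used for the advance rates of the spring
#' zero-crossing and trough dates.
#'
#' @param year calendar years (>= 5).
#' @param doy day-of-year values.
#' @return list with `slope` (day per year), `se` and `p`.
#' @export
date_trend <- function(year, doy) {
  stopifnot(length(year) == length(doy))
  if (length(year) < 5L) stop("need at least 5 years for a date trend")
  fit <- stats::lm(doy ~ year)
  slope <- unname(stats::coef(fit)["year"])
  if (sum(stats::resid(fit)^2) < 1e-20 * max(1, sum(doy^2))) {
    # exact linear relation: zero residual variance
    return(list(slope = slope, se = 0,
                p = if (abs(slope) > 0) 0 else 1))
  }
  sm <- summary(fit)$coefficients
  list(slope = unname(sm["year", "Estimate"]),
       se = unname(sm["year", "Std. Error"]),
       p = unname(sm["year", "Pr(>|t|)"]))
}
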