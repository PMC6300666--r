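# Internal noleap-calendar helpers. The whole package works on a 365-day
# year (Feb 29 dropped on input), so day-of-year windows are stable across
# years and a daily axis is simply (year - year0) * 365 + doy - 1.

.MONTH_DAYS <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
.MONTH_START <- c(0L, cumsum(.MONTH_DAYS))[1:12]  # doy of month start - 1

# July 1-7 and August 25-31 in the noleap calendar
.DOY_JUL1 <- 182L
.DOY_JUL7 <- 188L
.DOY_AUG25 <- 237L
.DOY_AUG31 <- 243L
.DOY_SUMMER <- 182L:243L  # July + August

noleap_doy <- function(month, day) {
  stopifnot(all(month >= 1L & month <= 12L))
  .MONTH_START[month] + day
}

doy_to_month <- function(doy) {
  findInterval(doy, c(.MONTH_START + 1L), rightmost.closed = FALSE)
}

#' Build the daily noleap time axis for a span of years
#'
#' @param years integer vector of consecutive calendar years.
#' @return data frame with columns `year`, `doy` (1-365) and `t`, the day
#'   index counted from 1 January of the first year (day 0).
#' @keywords internal
daily_axis <- function(years) {
  years <- as.integer(years)
  stopifnot(all(diff(years) == 1L))
  data.frame(
    year = rep(years, each = 365L),
    doy = rep.int(1:365, length(years)),
    t = seq(0L, length(years) * 365L - 1L)
  )
}

# absolute day index for (year, doy) given the axis origin year
abs_day <- function(year, doy, year0) (year - year0) * 365 + doy - 1
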