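#' Construct a CO2 concentration series
#'
#' The basic container for a station CO2 record on the package's 365-day
#' calendar. A series is a data frame with one row per observation slot,
#' columns `year`, `doy`, `t` (days since 1 January of the first year),
#' `conc` (ppm) and `flag` (one of `"retained"`, `"missing"`,
#' `"outlier"`), and a `cadence` attribute (`"daily"` or `"weekly"`).
#'
#' @param year,doy integer vectors; `doy` is day-of-year 1-365 (no Feb 29).
#' @param conc numeric, ppm; may be `NA` where `flag != "retained"`.
#' @param flag character QC flag per record; defaults to `"retained"`
#'   where `conc` is finite, `"missing"` otherwise.
#' @param cadence `"daily"` or `"weekly"`. Timestamps must be strictly
#'   increasing and uniformly spaced (1 or 7 days) over non-missing slots;
#'   mixed cadence is rejected.
#' @return an object of class `co2_series`.
#' @export
co2_series <- function(year, doy, conc, flag = NULL,
                       cadence = c("daily", "weekly")) {
  cadence <- match.arg(cadence)
  year <- as.integer(year)
  doy <- as.integer(doy)
  conc <- as.numeric(conc)
  if (length(year) != length(doy) || length(year) != length(conc)) {
    stop("year, doy and conc must have equal length")
  }
  if (any(doy < 1L | doy > 365L)) stop("doy must be in 1..365")
  if (is.null(flag)) {
    flag <- ifelse(is.finite(conc), "retained", "missing")
  }
  flag <- as.character(flag)
  if (!all(flag %in% c("retained", "missing", "outlier"))) {
    stop("flag must be one of 'retained', 'missing', 'outlier'")
  }
  if (any(flag == "retained" & !is.finite(conc))) {
    stop("conc must be finite where flag == 'retained'")
  }
  t <- abs_day(year, doy, year[1L])
  if (any(diff(t) <= 0)) stop("timestamps must be strictly increasing")
  step <- if (cadence == "daily") 1L else 7L
  if (length(t) > 1L && any(diff(t) %% step != 0)) {
    stop("timestamps are not on a uniform ", cadence, " grid")
  }
  x <- data.frame(year = year, doy = doy, t = t, conc = conc,
                  flag = flag, stringsAsFactors = FALSE)
  structure(x, class = c("co2_series", "data.frame"), cadence = cadence)
}

#' @export
print.co2_series <- function(x, ...) {
  n_ret <- sum(x$flag == "retained")
  cat(sprintf("<co2_series> %s cadence, %d records (%d retained), %d-%d\n",
              attr(x, "cadence"), nrow(x), n_ret, x$year[1L],
              x$year[nrow(x)]))
  invisible(x)
}

retained <- function(series) series[series$flag == "retained", , drop = FALSE]

#' Read a CO2 record from disk
#'
#' Parses station CO2 text files into a [co2_series()]. Three dialects are
#' supported:
#' \describe{
#'   \item{`noaa-insitu-daily`}{whitespace-separated columns
#'     `year month day value ...`; `-999.99` marks missing values;
#'     lines starting with `#` are comments.}
#'   \item{`globalview-weekly`}{same column layout at weekly cadence
#'     (week-midpoint dates), `-999.99` sentinel.}
#'   \item{`csv`}{header `date,conc` with ISO dates.}
#' }
#' February 29 records are dropped so that day-of-year windows are stable
#' across leap years.
#'
#' @param path file path.
#' @param dialect one of `"noaa-insitu-daily"`, `"globalview-weekly"`,
#'   `"csv"`.
#' @return a [co2_series()].
#' @export
read_co2 <- function(path,
                     dialect = c("noaa-insitu-daily", "globalview-weekly",
                                 "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines_keep <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  if (length(lines_keep) == 0L) stop("empty file: ", path)

  if (dialect == "csv") {
    hdr <- tolower(trimws(strsplit(lines[lines_keep[1L]], ",")[[1L]]))
    if (!identical(hdr[1:2], c("date", "conc"))) {
      stop("line ", lines_keep[1L], ": expected header 'date,conc'")
    }
    body <- lines_keep[-1L]
    if (length(body) == 0L) stop("empty file: ", path)
    parts <- strsplit(lines[body], ",")
    bad <- which(vapply(parts, length, 1L) < 2L)
    if (length(bad)) stop("line ", body[bad[1L]], ": unparseable record")
    dates <- as.Date(vapply(parts, `[[`, "", 1L))
    if (anyNA(dates)) {
      stop("line ", body[which(is.na(dates))[1L]], ": unparseable date")
    }
    vals <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
    ymd <- data.frame(year = as.integer(format(dates, "%Y")),
                      month = as.integer(format(dates, "%m")),
                      day = as.integer(format(dates, "%d")),
                      value = vals)
  } else {
    parts <- strsplit(trimws(lines[lines_keep]), "\\s+")
    bad <- which(vapply(parts, length, 1L) < 4L)
    if (length(bad)) stop("line ", lines_keep[bad[1L]], ": unparseable record")
    num <- function(i) suppressWarnings(as.numeric(vapply(parts, `[[`, "", i)))
    ymd <- data.frame(year = as.integer(num(1L)), month = as.integer(num(2L)),
                      day = as.integer(num(3L)), value = num(4L))
    bad <- which(!is.finite(ymd$year) | !is.finite(ymd$month))
    if (length(bad)) stop("line ", lines_keep[bad[1L]], ": unparseable record")
  }

  keep <- !(ymd$month == 2L & ymd$day == 29L)
  ymd <- ymd[keep, , drop = FALSE]
  if (nrow(ymd) == 0L) stop("no usable records in ", path)
  val <- ymd$value
  val[!is.na(val) & abs(val + 999.99) < 1e-6] <- NA_real_
  cadence <- if (dialect == "globalview-weekly") "weekly" else "daily"
  doy <- noleap_doy(ymd$month, ymd$day)
  t <- abs_day(ymd$year, doy, ymd$year[1L])
  if (any(diff(t) <= 0)) {
    stop("non-monotone dates at record ", which(diff(t) <= 0)[1L] + 1L)
  }
  co2_series(ymd$year, doy, val, cadence = cadence)
}

#' Write a CO2 series as CSV
#'
#' Inverse of the `csv` dialect of [read_co2()]: columns `date,conc,flag`
#' with concentrations printed at 0.01 ppm precision (the format's native
#' precision) and `-999.99` for non-retained records.
#'
#' @param series a [co2_series()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_co2 <- function(series, path) {
  stopifnot(inherits(series, "co2_series"))
  month <- doy_to_month(series$doy)
  day <- series$doy - .MONTH_START[month]
  date <- sprintf("%04d-%02d-%02d", series$year, month, day)
  conc <- ifelse(series$flag == "retained",
                 sprintf("%.2f", series$conc), "-999.99")
  writeLines(c("date,conc,flag", paste(date, conc, series$flag, sep = ",")),
             path)
  invisible(path)
}
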