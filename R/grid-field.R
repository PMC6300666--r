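#' Construct a gridded field
#'
#' A regular lat-lon field with a time dimension, the container for
#' climate, vegetation and footprint grids. `values` is an array with
#' dimensions `(lat, lon, time)`; static fields (a footprint, a mask, a
#' climatology) use a single time slice.
#'
#' @param lat,lon grid-cell centre coordinates in degrees; `lat` within
#'   \[-90, 90\], both regularly spaced.
#' @param time data frame describing the time slices: columns `year` and
#'   optionally `month` (monthly fields) or `doy` (daily fields); or
#'   `NULL` for a static field.
#' @param values numeric array `(nlat, nlon, ntime)`; a matrix is
#'   accepted for a static field.
#' @param units units string (mandatory, e.g. `"degC"`, `"mm"`, `"%"`,
#'   `"1"`).
#' @param name variable name (e.g. `"temperature"`).
#' @return object of class `grid_field`.
#' @export
grid_field <- function(lat, lon, time, values, units, name = "field") {
  lat <- as.numeric(lat); lon <- as.numeric(lon)
  if (any(lat < -90 | lat > 90)) stop("lat must be within [-90, 90]")
  check_regular <- function(v, lab) {
    if (length(v) > 2L && max(abs(diff(diff(v)))) > 1e-8) {
      stop(lab, " is not a regular grid")
    }
  }
  check_regular(lat, "lat"); check_regular(lon, "lon")
  if (missing(units) || is.null(units)) stop("units attribute is required")
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  ntime <- if (is.null(time)) 1L else nrow(time)
  if (!identical(dim(values), c(length(lat), length(lon), ntime))) {
    stop("values must be an array (nlat, nlon, ntime) = (",
         length(lat), ", ", length(lon), ", ", ntime, ")")
  }
  structure(list(lat = lat, lon = lon, time = time, values = values,
                 units = units, name = name),
            class = "grid_field")
}

#' @export
print.grid_field <- function(x, ...) {
  cat(sprintf("<grid_field> %s [%s]: %d x %d grid, %d time slice(s)\n",
              x$name, x$units, length(x$lat), length(x$lon),
              dim(x$values)[3L]))
  invisible(x)
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a$lat, b$lat, tolerance = 1e-8)) &&
    isTRUE(all.equal(a$lon, b$lon, tolerance = 1e-8))
}

stop_grid_mismatch <- function(a, b) {
  if (!same_grid(a, b)) stop("fields are not on the same grid")
}

# select the time slices matching the given year (and months/doys)
slice_index <- function(field, year, month = NULL, doy = NULL) {
  tm <- field$time
  if (is.null(tm)) stop("field has no time dimension")
  i <- which(tm$year == year)
  if (!is.null(month)) i <- i[tm$month[i] %in% month]
  if (!is.null(doy)) i <- i[tm$doy[i] %in% doy]
  i
}

#' Write a gridded field to CF-NetCDF
#'
#' Dimensions `time`, `lat`, `lon`; the time coordinate is days since
#' 1 January of the field's first year on a `noleap` (365-day) calendar,
#' with `units` attributes on every variable.
#'
#' @param field a [grid_field()].
#' @param path output `.nc` path.
#' @return `path`, invisibly.
#' @export
write_grid_nc <- function(field, path) {
  stopifnot(inherits(field, "grid_field"))
  tm <- field$time
  if (is.null(tm)) tm <- data.frame(year = 1L)
  year0 <- tm$year[1L]
  tvals <- if (!is.null(tm$doy)) {
    abs_day(tm$year, tm$doy, year0)
  } else if (!is.null(tm$month)) {
    abs_day(tm$year, noleap_doy(tm$month, 15L), year0)
  } else {
    abs_day(tm$year, 183L, year0)
  }
  dim_lat <- ncdf4::ncdim_def("lat", "degrees_north", field$lat)
  dim_lon <- ncdf4::ncdim_def("lon", "degrees_east", field$lon)
  dim_time <- ncdf4::ncdim_def(
    "time", sprintf("days since %04d-01-01", year0), as.double(tvals),
    unlim = TRUE, calendar = "noleap")
  var <- ncdf4::ncvar_def(field$name, field$units,
                          list(dim_lat, dim_lon, dim_time),
                          missval = -9999, prec = "double")
  nc <- ncdf4::nc_create(path, var)
  on.exit(ncdf4::nc_close(nc))
  ncdf4::ncvar_put(nc, var, field$values)
  ncdf4::ncatt_put(nc, 0, "Conventions", "CF-1.8")
  invisible(path)
}

#' Read a gridded field from CF-NetCDF
#'
#' @param path `.nc` file written by [write_grid_nc()] or any file with
#'   `lat`, `lon`, `time` dimensions and a units attribute.
#' @param name variable to read; default: the first non-coordinate
#'   variable.
#' @return a [grid_field()].
#' @export
read_grid_nc <- function(path, name = NULL) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  if (is.null(name)) name <- names(nc$var)[1L]
  lat <- as.numeric(ncdf4::ncvar_get(nc, "lat"))
  lon <- as.numeric(ncdf4::ncvar_get(nc, "lon"))
  tdim <- nc$dim$time
  tunits <- tdim$units
  m <- regmatches(tunits, regexec("days since ([0-9]{1,4})-", tunits))[[1L]]
  if (length(m) < 2L) stop("unsupported time units: ", tunits)
  year0 <- as.integer(m[2L])
  tvals <- as.numeric(tdim$vals)
  year <- year0 + tvals %/% 365
  doy <- tvals %% 365 + 1
  time <- data.frame(year = as.integer(year), doy = as.integer(doy),
                     month = doy_to_month(as.integer(doy)))
  vals <- ncdf4::ncvar_get(nc, name, collapse_degen = FALSE)
  units <- ncdf4::ncatt_get(nc, name, "units")$value
  grid_field(lat, lon, time, array(vals, c(length(lat), length(lon),
                                           length(tvals))),
             units = units, name = name)
}
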