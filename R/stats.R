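# The statistical core: detrended partial correlations with controls,
# subsample resampling distributions, regression sensitivities, period
# comparisons, moving windows, lags and pixelwise maps.

as_control_matrix <- function(controls, n) {
  if (is.null(controls) || length(controls) == 0L) {
    return(matrix(numeric(0), n, 0L))
  }
  if (is.list(controls) && !is.data.frame(controls)) {
    controls <- do.call(cbind, controls)
  }
  z <- as.matrix(controls)
  if (nrow(z) != n) stop("controls must have the same length as y and x")
  z
}

#' Remove a linear trend in year
#'
#' Residuals of an ordinary least-squares fit on calendar year; the
#' standard preparation of every per-period series before correlation.
#'
#' @param x numeric values.
#' @param year calendar years (default: an index); at least 4 points.
#' @return numeric anomalies with mean zero (to machine precision).
#' @export
detrend_linear <- function(x, year = seq_along(x)) {
  if (length(x) < 4L) stop("need at least 4 points to detrend")
  stopifnot(length(x) == length(year))
  unname(stats::resid(stats::lm(x ~ year)))
}

residualize <- function(v, z) {
  if (ncol(z) == 0L) return(v - mean(v))
  unname(stats::lm.fit(cbind(1, z), v)$residuals)
}

#' Partial correlation with control variables
#'
#' Pearson correlation between the residuals of `y` and `x` after
#' regressing each on the controls (with intercept). The two-sided
#' p-value uses `t = r sqrt((n - 2 - k) / (1 - r^2))` on `n - 2 - k`
#' degrees of freedom, `k` the number of controls. With no controls this
#' reduces to the plain Pearson correlation test.
#'
#' @param y,x numeric vectors of equal length.
#' @param controls `NULL`, a numeric matrix, data frame or list of
#'   control series (e.g. precipitation and cloudiness; optionally also
#'   sea-ice extent or mean summer temperature).
#' @param y_name,x_name labels recorded on the result.
#' @return object of class `partial_corr`: list with `r`, `p`, `n`, `k`,
#'   `df`, `y_name`, `x_name`, `controls` (labels).
#' @export
partial_correlation <- function(y, x, controls = NULL,
                                y_name = "y", x_name = "x") {
  n <- length(y)
  if (length(x) != n) stop("y and x must have equal length")
  z <- as_control_matrix(controls, n)
  k <- ncol(z)
  if (n <= k + 2L) stop("sample too small for ", k, " controls")
  if (k > 0L) {
    if (kappa(cbind(1, z), exact = TRUE) > 1e10 ||
        kappa(cbind(1, z, x), exact = TRUE) > 1e10) {
      stop("controls are collinear (condition number > 1e10)")
    }
  }
  ry <- residualize(y, z)
  rx <- residualize(x, z)
  r <- sum(ry * rx) / sqrt(sum(ry^2) * sum(rx^2))
  r <- max(-1, min(1, r))
  df <- n - 2L - k
  p <- if (abs(r) >= 1) 0 else {
    tt <- r * sqrt(df / (1 - r^2))
    2 * stats::pt(-abs(tt), df)
  }
  labels <- colnames(z)
  if (k > 0L && is.null(labels)) labels <- paste0("c", seq_len(k))
  structure(list(r = r, p = p, n = n, k = k, df = df,
                 y_name = y_name, x_name = x_name, controls = labels),
            class = "partial_corr")
}

#' @export
print.partial_corr <- function(x, ...) {
  ctrl <- if (x$k) paste(x$controls, collapse = ", ") else "none"
  cat(sprintf("<partial_corr> r(%s, %s | %s) = %.3f, p = %.3g, n = %d\n",
              x$y_name, x$x_name, ctrl, x$r, x$p, x$n))
  invisible(x)
}

#' Subsample distribution of a partial correlation
#'
#' Draws subsets of `m` of the `n` years (without replacement),
#' recomputes the partial correlation on each, and summarises the
#' distribution; its standard deviation is the error bar on the
#' correlation. When the number of distinct subsets `choose(n, m)` is
#' small (at most `exhaustive_limit`) all subsets are enumerated;
#' otherwise `n_draws` random subsets are drawn under `seed`.
#'
#' @param y,x,controls as in [partial_correlation()].
#' @param m subsample size (e.g. 14 of 17 years, or 11 of 14).
#' @param n_draws random draws when not enumerating (default 1000).
#' @param seed integer seed for the random draws.
#' @param method `"auto"`, `"exhaustive"` or `"random"`.
#' @param exhaustive_limit largest subset count that is enumerated under
#'   `"auto"`.
#' @return object of class `subsample_dist`: list with `draws`, `m`,
#'   `n`, `n_draws`, `mean`, `sd`, `method`, `full` (the full-sample
#'   [partial_correlation()] result, whose p-value is the reported
#'   significance).
#' @export
subsample_partial_correlation <- function(y, x, controls = NULL, m,
                                          n_draws = 1000L, seed = 1L,
                                          method = c("auto", "exhaustive",
                                                     "random"),
                                          exhaustive_limit = 5000L) {
  method <- match.arg(method)
  n <- length(y)
  z <- as_control_matrix(controls, n)
  if (m > n) stop("m cannot exceed the sample size")
  if (m < ncol(z) + 4L) stop("m too small for ", ncol(z), " controls")
  n_subsets <- choose(n, m)
  if (method == "auto") {
    method <- if (n_subsets <= exhaustive_limit) "exhaustive" else "random"
  }
  pc_of <- function(idx) {
    partial_correlation(y[idx], x[idx],
                        if (ncol(z)) z[idx, , drop = FALSE] else NULL)$r
  }
  if (method == "exhaustive") {
    draws <- utils::combn(n, m, FUN = pc_of)
  } else {
    idx <- withr_seed(seed, {
      replicate(n_draws, sort(sample.int(n, m)), simplify = FALSE)
    })
    draws <- vapply(idx, pc_of, numeric(1L))
  }
  draws <- as.numeric(draws)
  structure(list(draws = draws, m = m, n = n,
                 n_draws = length(draws), mean = mean(draws),
                 sd = if (length(draws) > 1L) stats::sd(draws) else 0,
                 method = method,
                 full = partial_correlation(y, x, controls)),
            class = "subsample_dist")
}

# evaluate expr under a local RNG seed without touching the global stream
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' @export
print.subsample_dist <- function(x, ...) {
  cat(sprintf(
    "<subsample_dist> %d-of-%d (%s, %d draws): r = %.3f +- %.3f\n",
    x$m, x$n, x$method, x$n_draws, x$mean, x$sd))
  invisible(x)
}

#' Regression sensitivity of a response to temperature
#'
#' Slope on the first predictor (temperature) in a multiple OLS
#' regression of the response on temperature, precipitation and cloud
#' cover -- the interannual sensitivity gamma, in response units per
#' degree C when the response is drawdown.
#'
#' @param y response (e.g. detrended per-year drawdown, ppm).
#' @param predictors numeric matrix, data frame or list; the first
#'   column is temperature.
#' @return object of class `sensitivity_slope`: list with `gamma`, `se`,
#'   `p`, `n`, `predictors` (labels).
#' @export
sensitivity_slope <- function(y, predictors) {
  if (is.list(predictors) && !is.data.frame(predictors)) {
    predictors <- do.call(cbind, predictors)
  }
  X <- as.matrix(predictors)
  n <- length(y)
  if (nrow(X) != n) stop("predictors must match the length of y")
  if (n <= ncol(X) + 2L) stop("sample too small for ", ncol(X), " predictors")
  if (kappa(cbind(1, X), exact = TRUE) > 1e10) {
    stop("predictors are collinear (condition number > 1e10)")
  }
  fit <- stats::lm(y ~ X)
  rss <- sum(stats::resid(fit)^2)
  est <- unname(stats::coef(fit)[2L])
  if (rss < 1e-20 * max(1, sum(y^2))) {
    # exact linear dependence: zero residual variance
    return(structure(list(gamma = est, se = 0, p = 0, n = n,
                          predictors = colnames(X)),
                     class = "sensitivity_slope"))
  }
  sm <- summary(fit)$coefficients
  structure(list(gamma = est, se = unname(sm[2L, "Std. Error"]),
                 p = unname(sm[2L, "Pr(>|t|)"]), n = n,
                 predictors = colnames(X)),
            class = "sensitivity_slope")
}

#' @export
print.sensitivity_slope <- function(x, ...) {
  cat(sprintf("<sensitivity_slope> gamma = %.3f +- %.3f, p = %.3g, n = %d\n",
              x$gamma, x$se, x$p, x$n))
  invisible(x)
}

#' Compare a statistic between two periods
#'
#' For two subsample distributions: Welch's two-sample t-test on the two
#' draw sets. For two regression sensitivities: a z-test on the
#' difference of coefficients using their standard errors. Degenerate
#' case (both spreads zero): p is 1 when the means agree, 0 otherwise.
#'
#' @param d1,d2 two `subsample_dist` or two `sensitivity_slope` objects.
#' @return list with `p`, `statistic`, `estimate` (the two means or
#'   slopes) and `test` (`"welch-t"` or `"z"`).
#' @export
compare_periods <- function(d1, d2) {
  if (inherits(d1, "subsample_dist") && inherits(d2, "subsample_dist")) {
    m1 <- d1$mean; m2 <- d2$mean
    if (d1$sd == 0 && d2$sd == 0) {
      return(list(p = as.numeric(isTRUE(all.equal(m1, m2))) * 1,
                  statistic = NA_real_, estimate = c(m1, m2),
                  test = "welch-t"))
    }
    tt <- stats::t.test(d1$draws, d2$draws, var.equal = FALSE)
    list(p = tt$p.value, statistic = unname(tt$statistic),
         estimate = c(m1, m2), test = "welch-t")
  } else if (inherits(d1, "sensitivity_slope") &&
             inherits(d2, "sensitivity_slope")) {
    se <- sqrt(d1$se^2 + d2$se^2)
    if (se == 0) {
      return(list(p = as.numeric(isTRUE(all.equal(d1$gamma, d2$gamma))),
                  statistic = NA_real_, estimate = c(d1$gamma, d2$gamma),
                  test = "z"))
    }
    zst <- (d1$gamma - d2$gamma) / se
    list(p = 2 * stats::pnorm(-abs(zst)), statistic = zst,
         estimate = c(d1$gamma, d2$gamma), test = "z")
  } else {
    stop("d1 and d2 must both be subsample distributions or both slopes")
  }
}

#' Moving-window partial correlation and its trend
#'
#' Partial correlation computed in windows of `window` consecutive years
#' advanced one year at a time, each window detrended independently --
#' the diagnostic for a gradual change in the coupling. Because
#' consecutive windows share all but one year, the window correlations
#' are strongly autocorrelated and an ordinary regression p-value for
#' the trend in r is severely anti-conservative; the trend is therefore
#' tested by permutation: the (y, x, controls) year-tuples are shuffled
#' jointly (which preserves the coupling but destroys any time ordering)
#' and the observed OLS slope of r on window-centre year is compared
#' with the permutation distribution, two-sided.
#'
#' @param year calendar years (consecutive).
#' @param y,x,controls as in [partial_correlation()]; controls are
#'   detrended within each window alongside y and x.
#' @param window window length in years (default 15).
#' @param n_perm permutations for the trend test.
#' @param seed seed for the permutation draws.
#' @param alternative `"two.sided"` (default), or `"less"` /
#'   `"greater"` when the hypothesis is a directional change in the
#'   coupling (e.g. `"less"` for a declining r).
#' @return list with `windows` (data frame `center`, `start`, `end`,
#'   `r`, `p`) and `trend` (list `slope` in r per year, `se` (OLS),
#'   `p` (permutation), `n_perm`, `alternative`).
#' @export
moving_window_correlation <- function(year, y, x, controls = NULL,
                                      window = 15L, n_perm = 199L,
                                      seed = 1L,
                                      alternative = c("two.sided", "less",
                                                      "greater")) {
  alternative <- match.arg(alternative)
  n <- length(year)
  if (n < window) stop("series shorter than the window")
  z <- as_control_matrix(controls, n)
  k <- ncol(z)
  starts <- seq_len(n - window + 1L)
  win_r <- function(yy, xx, zz) {
    vapply(starts, function(s) {
      i <- s:(s + window - 1L)
      window_partial_r(yy[i], xx[i], zz[i, , drop = FALSE], year[i])
    }, numeric(1L))
  }
  r <- win_r(y, x, z)
  centers <- year[starts] + (window - 1) / 2
  df <- window - 2L - k
  tstat <- r * sqrt(df / pmax(1 - r^2, 1e-15))
  p_win <- 2 * stats::pt(-abs(tstat), df)
  cc <- centers - mean(centers)
  slope_of <- function(rv) sum(cc * rv) / sum(cc^2)
  obs <- slope_of(r)
  perm <- withr_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(n)
      slope_of(win_r(y[idx], x[idx], z[idx, , drop = FALSE]))
    }, numeric(1L))
  })
  p_perm <- switch(alternative,
                   two.sided = (1 + sum(abs(perm) >= abs(obs))) / (n_perm + 1),
                   less = (1 + sum(perm <= obs)) / (n_perm + 1),
                   greater = (1 + sum(perm >= obs)) / (n_perm + 1))
  res <- r - mean(r) - obs * cc
  se <- sqrt(sum(res^2) / (length(r) - 2L) / sum(cc^2))
  list(windows = data.frame(center = centers, start = year[starts],
                            end = year[starts + window - 1L],
                            r = r, p = p_win),
       trend = list(slope = obs, se = se, p = p_perm, n_perm = n_perm,
                    alternative = alternative))
}

# fast within-window detrended partial correlation (hot path of the
# permutation test): linear detrend in time, residualise on controls,
# Pearson r
window_partial_r <- function(y, x, z, t) {
  tc <- t - mean(t)
  stc <- sum(tc^2)
  dt <- function(v) v - mean(v) - (sum(tc * v) / stc) * tc
  y <- dt(y)
  x <- dt(x)
  if (ncol(z)) {
    q <- qr(cbind(1, apply(z, 2L, dt)))
    y <- qr.resid(q, y)
    x <- qr.resid(q, x)
  }
  sum(y * x) / sqrt(sum(y^2) * sum(x^2))
}

#' Lagged partial correlation
#'
#' Correlates `y` in year t with `x` in year t - lag (controls stay
#' contemporaneous with `y`), dropping years without a lagged partner.
#'
#' @param year calendar years of all series.
#' @param y,x,controls as in [partial_correlation()].
#' @param lag years of lag (0 reduces to [partial_correlation()]).
#' @param detrend detrend all aligned series first (default `TRUE`).
#' @return a [partial_correlation()] result.
#' @export
lagged_correlation <- function(year, y, x, controls = NULL, lag = 1L,
                               detrend = TRUE) {
  n <- length(year)
  z <- as_control_matrix(controls, n)
  j <- match(year - lag, year)        # index of x at year t - lag
  ok <- !is.na(j)
  if (sum(ok) < ncol(z) + 4L) stop("too few overlapping years after lagging")
  yy <- y[ok]
  xx <- x[j[ok]]
  zz <- if (ncol(z)) z[ok, , drop = FALSE] else NULL
  if (detrend) {
    yr <- year[ok]
    yy <- detrend_linear(yy, yr)
    xx <- detrend_linear(xx, yr)
    if (!is.null(zz)) zz <- apply(zz, 2L, detrend_linear, year = yr)
  }
  pc <- partial_correlation(yy, xx, zz, y_name = "y",
                            x_name = sprintf("x[t-%d]", lag))
  pc
}

#' Pixelwise partial-correlation map
#'
#' [partial_correlation()] applied per masked pixel of per-year summer
#' fields, every series detrended within the period first. Significance
#' is reported at the 0.05 and 0.1 levels.
#'
#' @param field_y,field_x arrays `(nlat, nlon, nyear)` or annual
#'   [grid_field()]s on the same grid.
#' @param control_fields list of like arrays/fields (may be empty).
#' @param years calendar years of the third dimension.
#' @param mask logical matrix of pixels to evaluate (default: all).
#' @return list of matrices `r`, `p`, `sig05`, `sig10` plus `n`.
#' @export
pixelwise_partial_correlation <- function(field_y, field_x,
                                          control_fields = list(),
                                          years, mask = NULL) {
  arr <- function(f) if (inherits(f, "grid_field")) f$values else f
  ay <- arr(field_y); ax <- arr(field_x)
  ac <- lapply(control_fields, arr)
  if (!identical(dim(ay), dim(ax))) stop("fields are not on the same grid")
  for (a in ac) if (!identical(dim(a), dim(ay))) stop("control grid mismatch")
  nlat <- dim(ay)[1L]; nlon <- dim(ay)[2L]
  stopifnot(dim(ay)[3L] == length(years))
  if (is.null(mask)) mask <- matrix(TRUE, nlat, nlon)
  rmap <- pmap <- matrix(NA_real_, nlat, nlon)
  for (i in seq_len(nlat)) {
    for (j in seq_len(nlon)) {
      if (!mask[i, j]) next
      yy <- ay[i, j, ]; xx <- ax[i, j, ]
      zz <- if (length(ac)) vapply(ac, function(a) a[i, j, ],
                                   numeric(length(years))) else NULL
      if (anyNA(yy) || anyNA(xx) || (length(zz) && anyNA(zz))) next
      yy <- detrend_linear(yy, years)
      xx <- detrend_linear(xx, years)
      if (!is.null(zz)) zz <- apply(zz, 2L, detrend_linear, year = years)
      pc <- try(partial_correlation(yy, xx, zz), silent = TRUE)
      if (inherits(pc, "try-error")) next
      rmap[i, j] <- pc$r
      pmap[i, j] <- pc$p
    }
  }
  list(r = rmap, p = pmap, sig05 = pmap < 0.05, sig10 = pmap < 0.1,
       n = length(years))
}

#' Difference between two correlation maps
#'
#' Change in pixelwise correlation from the earlier to the later period,
#' `later - earlier`.
#'
#' @param map_early,map_late results of
#'   [pixelwise_partial_correlation()].
#' @return matrix of r differences.
#' @export
period_difference <- function(map_early, map_late) {
  map_late$r - map_early$r
}
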