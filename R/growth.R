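# Growth kinetics and plasmid-stability quantification: specific growth
# rate from the exponential phase of a growth curve, automated selection of
# the log-linear window, and CFU-ratio plasmid retention.

#' Construct a growth curve
#'
#' @param times_h Strictly increasing sampling times in hours.
#' @param densities Positive cell densities (cells/ml or calibrated
#'   turbidity).
#' @param strain Text label.
#' @return An object of class `growth_curve`.
#' @export
growth_curve <- function(times_h, densities, strain = "") {
  stopifnot(is.numeric(times_h), is.numeric(densities),
            length(times_h) == length(densities))
  if (length(times_h) > 1L && any(diff(times_h) <= 0)) {
    stop("'times_h' must be strictly increasing", call. = FALSE)
  }
  if (any(densities <= 0)) {
    stop("'densities' must be positive", call. = FALSE)
  }
  structure(list(times_h = times_h, densities = densities, strain = strain),
            class = "growth_curve")
}

assert_curve <- function(curve) {
  if (!inherits(curve, "growth_curve")) {
    stop("expected a 'growth_curve' object", call. = FALSE)
  }
  invisible(curve)
}

# Closed-form simple linear regression; avoids summary.lm's noise on
# residual-free fits. Returns slope, its standard error and R^2 (NaN when
# the response is constant).
loglin_fit <- function(t, y) {
  n <- length(t)
  sxx <- sum((t - mean(t))^2)
  slope <- sum((t - mean(t)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(t)
  sse <- sum((y - intercept - slope * t)^2)
  sst <- sum((y - mean(y))^2)
  list(slope = slope,
       se = sqrt(sse / (n - 2) / sxx),
       r_squared = if (sst > 0) 1 - sse / sst else NaN)
}

#' Specific growth rate from the exponential phase
#'
#' Least-squares slope of `log2(density)` versus time over the requested
#' window, reported in divisions per hour with its standard error and R
#' squared. The literal linear slope of raw density versus time (units:
#' density per hour) is available with `log2_transform = FALSE` but does
#' not yield divisions per hour.
#'
#' @param curve A [growth_curve()].
#' @param window Time interval `c(from, to)` in hours; default the full
#'   curve. Must contain at least 3 points.
#' @param log2_transform Fit on `log2(density)` (default `TRUE`).
#' @return A list of class `growth_rate_fit`: `mu` (divisions/h), `se`,
#'   `r_squared`, `n_points`, `window`, `log2_transform`.
#' @examples
#' cv <- growth_curve(0:5, 1e6 * 2^(0:5))
#' specific_growth_rate(cv)$mu # 1 division/h
#' @export
specific_growth_rate <- function(curve, window = NULL,
                                 log2_transform = TRUE) {
  assert_curve(curve)
  if (is.null(window)) window <- range(curve$times_h)
  stopifnot(is.numeric(window), length(window) == 2L)
  sel <- curve$times_h >= window[1] & curve$times_h <= window[2]
  if (sum(sel) < 3L) {
    stop("growth-rate window must contain at least 3 points", call. = FALSE)
  }
  t <- curve$times_h[sel]
  y <- if (log2_transform) log2(curve$densities[sel]) else
    curve$densities[sel]
  fit <- loglin_fit(t, y)
  structure(
    list(mu = fit$slope,
         se = fit$se,
         r_squared = fit$r_squared,
         n_points = sum(sel),
         window = window,
         log2_transform = log2_transform),
    class = "growth_rate_fit"
  )
}

#' @export
print.growth_rate_fit <- function(x, ...) {
  cat(sprintf(
    "<growth_rate_fit> mu = %.3f %s (se %.3f, R^2 %.4f, n = %d, t in [%g, %g])\n",
    x$mu, if (x$log2_transform) "divisions/h" else "density/h",
    x$se, x$r_squared, x$n_points, x$window[1], x$window[2]))
  invisible(x)
}

#' Locate the exponential (log-linear) phase of a growth curve
#'
#' Finds the longest contiguous run of points whose log2-linear fit attains
#' `R^2 >= r2_min`; ties are broken toward the earlier run. This automates
#' the by-eye selection of the "linear portion" of a growth curve.
#'
#' @param curve A [growth_curve()] with at least 4 points.
#' @param r2_min Minimum R squared (default 0.99).
#' @param min_points Minimum run length (default 3).
#' @return Time interval `c(from, to)` in hours. When no run qualifies an
#'   error of class `topogel_window_not_found` is raised.
#' @export
exponential_window <- function(curve, r2_min = 0.99, min_points = 3) {
  assert_curve(curve)
  n <- length(curve$times_h)
  if (n < 4L) stop("need at least 4 points", call. = FALSE)
  stopifnot(min_points >= 3)
  y <- log2(curve$densities)
  t <- curve$times_h
  best <- NULL
  for (i in seq_len(n - min_points + 1L)) {
    for (j in seq(i + min_points - 1L, n)) {
      r2 <- loglin_fit(t[i:j], y[i:j])$r_squared
      if (is.finite(r2) && r2 >= r2_min) {
        len <- j - i + 1L
        if (is.null(best) || len > best$len) {
          best <- list(i = i, j = j, len = len)
        }
      }
    }
  }
  if (is.null(best)) {
    stop(structure(
      class = c("topogel_window_not_found", "error", "condition"),
      list(message = sprintf(
        "no contiguous run of >= %d points reaches R^2 >= %g", min_points,
        r2_min), call = NULL)))
  }
  c(t[best$i], t[best$j])
}

#' Construct a plasmid-retention CFU series
#'
#' Colony counts under selective and non-selective plating across serial
#' passages, indexed by cell generations.
#'
#' @param generations Generation numbers (e.g. `c(0, 24, 54, 84)`).
#' @param cfu_selective Non-negative CFU counts on selective medium.
#' @param cfu_nonselective Positive CFU counts on non-selective medium.
#' @return An object of class `retention_series`.
#' @export
retention_series <- function(generations, cfu_selective, cfu_nonselective) {
  stopifnot(is.numeric(generations), is.numeric(cfu_selective),
            is.numeric(cfu_nonselective),
            length(generations) == length(cfu_selective),
            length(generations) == length(cfu_nonselective),
            all(cfu_selective >= 0))
  if (any(cfu_nonselective <= 0)) {
    stop("'cfu_nonselective' counts must be positive", call. = FALSE)
  }
  structure(list(generations = generations,
                 cfu_selective = cfu_selective,
                 cfu_nonselective = cfu_nonselective),
            class = "retention_series")
}

#' Plasmid retention fractions over serial passages
#'
#' Per-timepoint retention `cfu_selective / cfu_nonselective`, clamped to
#' `[0, 1]` with a warning when plating noise pushes a ratio above 1.
#' Retention is invariant to any dilution applied equally to both counts.
#'
#' @param series A [retention_series()].
#' @return Data frame with columns `generations`, `retention`.
#' @examples
#' plasmid_retention(retention_series(c(0, 84), c(100, 50), c(100, 100)))
#' @export
plasmid_retention <- function(series) {
  if (!inherits(series, "retention_series")) {
    stop("expected a 'retention_series' object", call. = FALSE)
  }
  r <- series$cfu_selective / series$cfu_nonselective
  if (any(r > 1)) {
    warning(sum(r > 1), " retention value(s) > 1 clamped to 1 ",
            "(plating noise)", call. = FALSE)
    r <- pmin(r, 1)
  }
  data.frame(generations = series$generations, retention = r)
}
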