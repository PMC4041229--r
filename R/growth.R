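#' Construct an OD600 time series
#'
#' Lightweight container for one culture's blank-corrected OD600 readings.
#'
#' @param time_h Sampling times in hours, strictly increasing, first time
#'   >= 0. At least 3 points.
#' @param od Blank-corrected OD600 readings, same length as `time_h`.
#'   Small negative values (>= -0.05) are tolerated after blank
#'   subtraction.
#' @return An object of class `od_series`.
#' @export
od_series <- function(time_h, od) {
  if (length(time_h) < 3L || length(od) != length(time_h)) {
    abort_input("need >= 3 time points and matching od length")
  }
  if (any(!is.finite(time_h)) || time_h[1L] < 0 ||
      any(diff(time_h) <= 0)) {
    abort_input("time_h must be finite, start >= 0 and be strictly increasing")
  }
  if (any(!is.finite(od)) || any(od < -0.05)) {
    abort_input("od values must be finite and >= -0.05")
  }
  structure(list(time_h = as.numeric(time_h), od = as.numeric(od)),
            class = "od_series")
}

#' Detect the exponential-growth window of an OD600 series
#'
#' Scans all contiguous windows of at least `min_points` readings with
#' positive OD, fits ln(OD) against time in each, and keeps windows whose
#' linear fit reaches `r2_min` with a positive slope. Among those it
#' returns the window with the largest fitted slope; slope ties (to within
#' a relative 1e-9) go to the earliest, then longest, window -- so an
#' exactly exponential series returns its full span. Returns `NULL` when
#' no window qualifies, which callers treat as no detectable growth.
#'
#' The defaults require 5-point windows at R-squared 0.99. Shorter
#' windows or a laxer linearity filter let the maximum-slope selector
#' chase read noise, which is largest on the log scale at low OD early in
#' growth and inflates the estimated rate; 3-point windows are still
#' accepted when the series itself is that short.
#'
#' @param series An [od_series()] (or list with `time_h`, `od`).
#' @param min_points Minimum number of readings in a window (default 5;
#'   reduced to the series length, but never below 3, for short series).
#' @param r2_min Minimum R-squared of the ln(OD) linear fit (default
#'   0.99).
#' @return `NULL`, or a list with `t_start`, `t_end`, `idx` (indices into
#'   the series), `slope` and `r2`.
#' @export
detect_exponential_window <- function(series, min_points = 5L,
                                      r2_min = 0.99) {
  series <- as_od_series(series)
  keep <- which(series$od > 0)
  min_points <- max(3L, min(as.integer(min_points), length(keep)))
  if (length(keep) < min_points) {
    return(NULL)
  }
  tt <- series$time_h[keep]
  ly <- log(series$od[keep])
  n <- length(tt)

  best <- NULL
  for (i in seq_len(n - min_points + 1L)) {
    for (j in seq.int(i + min_points - 1L, n)) {
      f <- fast_linfit(tt[i:j], ly[i:j])
      if (!is.finite(f$slope) || f$slope <= 0 || f$r2 < r2_min) next
      if (is.null(best)) {
        best <- list(i = i, j = j, slope = f$slope, r2 = f$r2)
        next
      }
      tol <- 1e-9 * max(abs(best$slope), abs(f$slope))
      if (f$slope > best$slope + tol) {
        best <- list(i = i, j = j, slope = f$slope, r2 = f$r2)
      } else if (abs(f$slope - best$slope) <= tol) {
        # tie: earliest start, then longest span
        if (i < best$i || (i == best$i && (j - i) > (best$j - best$i))) {
          best <- list(i = i, j = j, slope = f$slope, r2 = f$r2)
        }
      }
    }
  }
  if (is.null(best)) {
    return(NULL)
  }
  idx <- keep[best$i:best$j]
  list(t_start = series$time_h[idx[1L]],
       t_end = series$time_h[idx[length(idx)]],
       idx = idx, slope = best$slope, r2 = best$r2)
}

#' Specific growth rate from an OD600 series
#'
#' Estimates the specific growth rate mu (per hour) as the least-squares
#' slope of ln(OD600) against time inside the exponential window. For an
#' exact exponential this equals the classical two-point form
#' ln(X_t / X_0) / t with time zero at the start of exponential growth.
#'
#' A growth rate of zero is assigned (with `zero_growth = TRUE`) when the
#' culture never exceeds OD 0.04, when readings decline overall (final
#' below initial reading and maximum rise under 0.02), or when no
#' exponential window can be found.
#'
#' @param series An [od_series()].
#' @param window Optional window: `NULL` to detect one with
#'   [detect_exponential_window()], or a numeric `c(t_start, t_end)` in
#'   hours.
#' @param min_points,r2_min Passed to the window detection; `min_points`
#'   is also the minimum number of usable (positive-OD) readings for a
#'   fit.
#' @return An object of class `growth_fit`: list with `mu` (1/h),
#'   `t_start`, `t_end`, `n_points`, `r2`, `zero_growth`, `max_od`.
#' @examples
#' s <- od_series(0:6, 0.05 * exp(0.5 * (0:6)))
#' fit_growth_rate(s)$mu  # 0.5
#' @export
fit_growth_rate <- function(series, window = NULL, min_points = 5L,
                            r2_min = 0.99) {
  series <- as_od_series(series)
  max_od <- max(series$od)

  zero_fit <- function() {
    structure(list(mu = 0, t_start = NA_real_, t_end = NA_real_,
                   n_points = 0L, r2 = NA_real_, zero_growth = TRUE,
                   max_od = max_od),
              class = "growth_fit")
  }

  od <- series$od
  declined <- od[length(od)] < od[1L] && (max_od - od[1L]) < 0.02
  if (max_od <= 0.04 || declined) {
    return(zero_fit())
  }

  if (is.null(window)) {
    w <- detect_exponential_window(series, min_points = min_points,
                                   r2_min = r2_min)
    if (is.null(w)) {
      return(zero_fit())
    }
    idx <- w$idx
  } else {
    if (!is.numeric(window) || length(window) != 2L ||
        window[1L] >= window[2L]) {
      abort_input("window must be c(t_start, t_end) with t_start < t_end")
    }
    idx <- which(series$time_h >= window[1L] & series$time_h <= window[2L] &
                   series$od > 0)
    if (length(idx) < 3L) {
      return(zero_fit())
    }
  }

  f <- fast_linfit(series$time_h[idx], log(series$od[idx]))
  if (!is.finite(f$slope) || f$slope <= 0) {
    return(zero_fit())
  }
  structure(list(mu = f$slope,
                 t_start = series$time_h[idx[1L]],
                 t_end = series$time_h[idx[length(idx)]],
                 n_points = length(idx), r2 = f$r2,
                 zero_growth = FALSE, max_od = max_od),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  if (x$zero_growth) {
    cat(sprintf("<growth_fit> zero growth (max OD %.3f)\n", x$max_od))
  } else {
    cat(sprintf(
      "<growth_fit> mu = %.4g /h over %.3g-%.3g h (%d points, R2 = %.4f)\n",
      x$mu, x$t_start, x$t_end, x$n_points, x$r2))
  }
  invisible(x)
}

#' Growth relative to no-solvent controls
#'
#' Expresses treated growth rates as percentages of the mean no-solvent
#' control rate mu0 (the control average is set at 100 percent).
#'
#' @param treated Growth rates of treated replicates: numeric vector or
#'   list of [fit_growth_rate()] results.
#' @param controls Growth rates of no-solvent control replicates, same
#'   forms. At least one control must have grown.
#' @return List with `mu0`, `percent` (per treated replicate),
#'   `mean_percent`, `sd_percent` (sample SD; `NA` with a single
#'   replicate).
#' @export
relative_growth <- function(treated, controls) {
  tr <- extract_mu(treated)
  ct <- extract_mu(controls)
  if (length(ct) < 1L) {
    abort_input("at least one control replicate is required")
  }
  mu0 <- mean(ct)
  if (mu0 <= 0) {
    abort_input("all no-solvent controls show zero growth; assay invalid")
  }
  pct <- 100 * tr / mu0
  list(mu0 = mu0, percent = pct, mean_percent = mean(pct),
       sd_percent = if (length(pct) >= 2L) stats::sd(pct) else NA_real_)
}

#' @keywords internal
#' @noRd
as_od_series <- function(x) {
  if (inherits(x, "od_series")) {
    return(x)
  }
  if (is.list(x) && all(c("time_h", "od") %in% names(x))) {
    return(od_series(x$time_h, x$od))
  }
  abort_input("expected an od_series (or list with time_h, od)")
}

#' @keywords internal
#' @noRd
extract_mu <- function(x) {
  if (is.numeric(x)) {
    return(as.numeric(x))
  }
  if (inherits(x, "growth_fit")) {
    return(x$mu)
  }
  if (is.list(x)) {
    return(vapply(x, function(g) {
      if (inherits(g, "growth_fit")) g$mu
      else if (is_number(g)) as.numeric(g)
      else abort_input("growth rates must be numbers or growth_fit objects")
    }, numeric(1)))
  }
  abort_input("growth rates must be numbers or growth_fit objects")
}
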