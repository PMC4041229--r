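#' Estimate an EC50 from a percent-of-control dose-response curve
#'
#' Finds the concentration halving the specific growth rate. The
#' no-solvent control contributes an implicit first point at
#' (0, 100 percent). Working up the concentration series:
#'
#' * if the culture shows no growth (0 percent) already at the lowest
#'   tested concentration, the EC50 is left-censored at that
#'   concentration;
#' * if the percent curve crosses 50 between two adjacent points, the
#'   EC50 is linear interpolation within the first bracketing segment
#'   (`method = "interpolated"`); an exact hit at a tested concentration
#'   returns that concentration;
#' * if growth stays above 50 percent everywhere, an ordinary
#'   least-squares line of percent against concentration (control
#'   included) is extrapolated to 50 (`method = "extrapolated"`) --
#'   provided a decline is actually evident, i.e. the fitted slope is
#'   negative and growth at the highest tested concentration has fallen
#'   below 80 percent of the control. Without an evident decline, or when
#'   the line reaches 50 at or below the highest tested concentration
#'   (contradicting the observed growth there), the EC50 is
#'   right-censored at the highest tested concentration. The 80 percent
#'   gate keeps the method from extrapolating a near-flat series many
#'   fold beyond the tested range.
#'
#' Percentages are floored at 0; stimulation above 100 percent is allowed
#' and handled by the crossing scan (the first downward crossing wins, a
#' conservative choice for non-monotone curves).
#'
#' @param conc Non-zero tested concentrations (mmol/L), strictly
#'   increasing, at least 2 values. Do not include the control at 0.
#' @param percent Growth as percent of the no-solvent control mu0 at each
#'   concentration.
#' @param include_control Include the implicit (0, 100) control point in
#'   interpolation and extrapolation (default `TRUE`).
#' @param scale Concentration scale of `conc`: `"aqueous"` (dissolved) or
#'   `"nominal"` (total per liquid volume; used above the solubility
#'   limit).
#' @return An object of class `ec50_estimate`: list with `value` (mmol/L;
#'   `NA` when censored), `censoring` one of `"point"`, `"left"`,
#'   `"right"`, `bound` (the censoring bound, `NA` for point estimates),
#'   `method` (`"interpolated"`, `"extrapolated"` or `NA`), and
#'   `concentration_scale`.
#' @examples
#' estimate_ec50(c(1, 2), c(80, 40))  # 1.75, interpolated
#' @export
estimate_ec50 <- function(conc, percent, include_control = TRUE,
                          scale = c("aqueous", "nominal")) {
  scale <- match.arg(scale)
  if (length(conc) != length(percent)) {
    abort_input("conc and percent must have the same length")
  }
  ok <- is.finite(conc) & is.finite(percent)
  conc <- conc[ok]
  percent <- pmax(0, percent[ok])
  if (length(unique(conc[conc > 0])) < 2L) {
    abort_input("need >= 2 distinct non-zero concentrations")
  }
  if (any(conc <= 0)) {
    abort_input("conc must be strictly positive; the control at 0 is implicit")
  }
  o <- order(conc)
  conc <- conc[o]
  percent <- percent[o]
  if (any(diff(conc) == 0)) {
    abort_input("concentrations must be distinct")
  }

  est <- function(value, censoring, bound, method) {
    structure(list(value = value, censoring = censoring, bound = bound,
                   method = method, concentration_scale = scale),
              class = "ec50_estimate")
  }

  # no growth at the lowest tested level: true EC50 lies below it
  if (percent[1L] == 0) {
    return(est(NA_real_, "left", conc[1L], NA_character_))
  }

  cc <- if (include_control) c(0, conc) else conc
  pp <- if (include_control) c(100, percent) else percent

  # first downward crossing of 50, scanning up the concentration axis
  for (i in seq_len(length(cc) - 1L)) {
    if (pp[i] >= 50 && pp[i + 1L] <= 50) {
      if (pp[i] == pp[i + 1L]) next  # flat at exactly 50: defer to next drop
      value <- cc[i] + (cc[i + 1L] - cc[i]) * (pp[i] - 50) / (pp[i] - pp[i + 1L])
      return(est(value, "point", NA_real_, "interpolated"))
    }
  }
  if (pp[length(pp)] == 50) {
    return(est(cc[length(cc)], "point", NA_real_, "interpolated"))
  }

  if (all(pp > 50)) {
    f <- fast_linfit(cc, pp)
    evident_decline <- percent[length(percent)] < 80
    if (is.finite(f$slope) && f$slope < 0 && evident_decline) {
      value <- (50 - f$intercept) / f$slope
      if (value > conc[length(conc)]) {
        return(est(value, "point", NA_real_, "extrapolated"))
      }
    }
    return(est(NA_real_, "right", conc[length(conc)], NA_character_))
  }

  # percents dipped to <50 without a >=50 point before them can only occur
  # when the control is excluded and the first tested point is below 50
  est(NA_real_, "left", conc[1L], NA_character_)
}

#' @export
print.ec50_estimate <- function(x, ...) {
  desc <- switch(x$censoring,
    point = sprintf("EC50 = %.4g mM (%s)", x$value, x$method),
    left = sprintf("EC50 < %.4g mM (left-censored)", x$bound),
    right = sprintf("EC50 > %.4g mM (right-censored)", x$bound))
  cat("<ec50_estimate> ", desc, " [", x$concentration_scale, " scale]\n",
      sep = "")
  invisible(x)
}

#' EC50 with replicate spread
#'
#' Estimates an EC50 for each replicate curve, then summarizes: majority
#' censoring class, mean and sample SD over the point estimates of the
#' replicates in that class. Replicates disagreeing with the majority
#' class are reported in `diagnostics`. An `"average"` mode instead
#' averages the percent values across replicates per concentration and
#' estimates a single EC50 from the averaged curve.
#'
#' @param curves List of replicate curves, each a list/data frame with
#'   elements `conc` and `percent` as for [estimate_ec50()].
#' @param mode `"replicate"` (default: estimate per replicate, then
#'   average) or `"average"` (average the curves, then estimate).
#' @param ... Passed to [estimate_ec50()].
#' @return An object of class `ec50_estimate` with additional fields
#'   `sd` (`NA` unless >= 2 point estimates), `n_replicates`, and
#'   `diagnostics` (character vector of censoring conflicts, if any).
#' @export
ec50_replicate_stats <- function(curves, mode = c("replicate", "average"),
                                 ...) {
  mode <- match.arg(mode)
  if (!is.list(curves) || length(curves) < 1L) {
    abort_input("curves must be a non-empty list of replicate curves")
  }

  if (mode == "average") {
    conc <- curves[[1L]]$conc
    for (cv in curves) {
      if (length(cv$conc) != length(conc) || any(cv$conc != conc)) {
        abort_input("average mode needs identical concentration series")
      }
    }
    pmat <- vapply(curves, function(cv) as.numeric(cv$percent),
                   numeric(length(conc)))
    out <- estimate_ec50(conc, rowMeans(pmat), ...)
    out$sd <- NA_real_
    out$n_replicates <- length(curves)
    out$diagnostics <- character(0)
    return(out)
  }

  ests <- lapply(curves, function(cv) estimate_ec50(cv$conc, cv$percent, ...))
  cls <- vapply(ests, function(e) e$censoring, character(1))
  tab <- sort(table(cls), decreasing = TRUE)
  major <- names(tab)[1L]
  diagnostics <- character(0)
  if (length(tab) > 1L) {
    diagnostics <- sprintf(
      "censoring disagreement across replicates: %s",
      paste(sprintf("%s x%d", names(tab), as.integer(tab)), collapse = ", "))
  }
  in_major <- ests[cls == major]
  if (major == "point") {
    vals <- vapply(in_major, function(e) e$value, numeric(1))
    methods <- vapply(in_major, function(e) e$method, character(1))
    out <- in_major[[1L]]
    out$value <- mean(vals)
    out$method <- if (any(methods == "extrapolated")) "extrapolated"
                  else "interpolated"
    out$sd <- if (length(vals) >= 2L) stats::sd(vals) else NA_real_
  } else {
    bounds <- vapply(in_major, function(e) e$bound, numeric(1))
    out <- in_major[[1L]]
    # replicates share the dose series, so bounds agree; keep the common one
    out$bound <- bounds[1L]
    out$sd <- NA_real_
  }
  out$n_replicates <- length(curves)
  out$diagnostics <- diagnostics
  out
}
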