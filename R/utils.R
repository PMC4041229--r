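# internal helpers shared across modules

#' @keywords internal
#' @noRd
abort_input <- function(...) {
  stop(paste0(...), call. = FALSE)
}

# Least-squares slope/intercept/R2 of y on x without lm() overhead.
# Used in the hot path of exponential-window scanning.
#' @keywords internal
#' @noRd
fast_linfit <- function(x, y) {
  n <- length(x)
  mx <- mean(x)
  my <- mean(y)
  dx <- x - mx
  dy <- y - my
  sxx <- sum(dx * dx)
  if (sxx <= 0) {
    return(list(slope = NA_real_, intercept = NA_real_, r2 = NA_real_, n = n))
  }
  slope <- sum(dx * dy) / sxx
  syy <- sum(dy * dy)
  r2 <- if (syy <= 0) 1 else (slope * slope * sxx) / syy
  list(slope = slope, intercept = my - slope * mx, r2 = r2, n = n)
}

#' @keywords internal
#' @noRd
is_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
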