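# Independent oracles used across test files.

# Brute-force EC50: piecewise-linear percent curve (control at 0,100),
# scanned on a dense grid for the first drop to 50, then refined by root
# finding on the linear interpolant. Independent of the analytical
# interpolation formula under test.
grid_ec50 <- function(conc, percent, n_grid = 1e4) {
  cc <- c(0, conc)
  pp <- c(100, pmax(0, percent))
  f <- stats::approxfun(cc, pp)
  grid <- seq(0, max(cc), length.out = n_grid)
  vals <- f(grid)
  below <- which(vals <= 50)
  if (!length(below)) {
    return(NA_real_)
  }
  i <- below[1L]
  if (i == 1L) {
    return(grid[1L])
  }
  stats::uniroot(function(x) f(x) - 50, c(grid[i - 1L], grid[i]),
                 tol = 1e-12)$root
}

# random strictly decreasing percent curve crossing 50 inside the range
random_monotone_curve <- function() {
  n <- sample(3:7, 1)
  conc <- sort(stats::runif(n, 0.1, 10))
  lo <- stats::runif(1, 0, 45)
  hi <- stats::runif(1, 55, 99)
  percent <- sort(stats::runif(n, lo, hi), decreasing = TRUE)
  percent[n] <- lo
  percent[1L] <- hi
  list(conc = conc, percent = percent)
}

# tiny ground-truth panel for fast pipeline tests
small_params <- function(shape = "linear", hill = 2) {
  p <- default_true_params(shape = shape, hill = hill)
  keep <- p$species$species[c(1, 4, 8)]
  list(species = p$species[p$species$species %in% keep, ],
       ec50 = p$ec50[p$ec50$species %in% keep, ])
}
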