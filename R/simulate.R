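#' Dose-response shapes used by the simulator
#'
#' Fraction of the solvent-free growth rate retained at dissolved
#' concentration `conc`. Both shapes satisfy f(0) = 1 and f(ec50) = 0.5
#' exactly:
#' * `"linear"`: `max(0, 1 - conc / (2 * ec50))`, reaching zero at twice
#'   the EC50;
#' * `"logistic"`: `1 / (1 + (conc / ec50)^hill)` (Hill curve).
#'
#' These shapes live only in the simulator; the analysis side assumes
#' nothing beyond a decline through 50 percent.
#'
#' @param conc Concentration(s), mmol/L, >= 0.
#' @param ec50 True EC50 in mmol/L, > 0.
#' @param shape `"linear"` or `"logistic"`.
#' @param hill Hill slope for the logistic shape (default 2).
#' @return Fraction(s) of mu0 in `[0, 1]`.
#' @export
dose_response_fraction <- function(conc, ec50,
                                   shape = c("linear", "logistic"),
                                   hill = 2) {
  shape <- match.arg(shape)
  if (!is_number(ec50) || ec50 <= 0) {
    abort_input("ec50 must be positive")
  }
  if (any(conc < 0)) {
    abort_input("conc must be >= 0")
  }
  if (shape == "linear") {
    pmax(0, 1 - conc / (2 * ec50))
  } else {
    1 / (1 + (conc / ec50)^hill)
  }
}

#' Simulation configuration
#'
#' Study-design parameters for the synthetic assay: five non-zero
#' concentrations per species-solvent pair plus a shared no-solvent
#' control, in triplicate, with additive Gaussian OD read noise.
#'
#' @param replicates Replicates per condition (default 3).
#' @param n_conc Non-zero concentrations per dose series (default 5).
#' @param conc_span Geometric span of the dose series: concentrations run
#'   from `ec50/conc_span` to `ec50 * conc_span` (default 4, bracketing
#'   the 50 percent point).
#' @param n_times OD readings per culture (default 12).
#' @param noise_sd SD of additive Gaussian OD noise (default 0.005;
#'   readings are truncated at 0).
#' @param seed Mandatory integer seed for reproducibility.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(replicates = 3L, n_conc = 5L, conc_span = 4,
                       n_times = 12L, noise_sd = 0.005, seed) {
  if (missing(seed) || !is_number(seed)) {
    abort_input("seed is mandatory: simulations must be reproducible")
  }
  if (replicates < 1L || n_conc < 2L || n_times < 3L) {
    abort_input("need replicates >= 1, n_conc >= 2, n_times >= 3")
  }
  if (!is_number(noise_sd) || noise_sd < 0) {
    abort_input("noise_sd must be >= 0")
  }
  if (!is_number(conc_span) || conc_span <= 1) {
    abort_input("conc_span must be > 1")
  }
  structure(list(replicates = as.integer(replicates),
                 n_conc = as.integer(n_conc), conc_span = conc_span,
                 n_times = as.integer(n_times), noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Geometric dose series bracketing a target EC50
#'
#' @param ec50 Target concentration to bracket, mmol/L.
#' @param n Number of concentrations (default 5).
#' @param span Ratio between the target and the series endpoints
#'   (default 4).
#' @return Increasing vector of `n` concentrations centred on `ec50`.
#' @export
dose_series <- function(ec50, n = 5L, span = 4) {
  if (!is_number(ec50) || ec50 <= 0) {
    abort_input("ec50 must be positive")
  }
  exp(seq(log(ec50 / span), log(ec50 * span), length.out = n))
}

#' Default ground-truth panel for the simulator
#'
#' Eight synthetic species spanning the observed range of anaerobic
#' growth rates (about 0.06 to 0.7 per hour, i.e. stationary phase
#' reached between roughly 5 and 70 hours), each paired with four
#' solvents whose true EC50s scale with the species' growth rate --
#' faster growers are more tolerant -- around per-solvent base levels
#' matching the toxicity order PCE/CT more toxic than CF, CF more toxic
#' than DCA. All species share the phase structure of the assay:
#' inoculation to about OD 0.02, a lag, exponential growth, then an
#' abrupt stationary plateau near OD 0.5.
#'
#' @param shape Dose-response shape given to every pair (default
#'   `"linear"`).
#' @param hill Hill slope when `shape = "logistic"`.
#' @return List with `species` (tibble: species, mu0_true, lag_h, od0,
#'   od_max) and `ec50` (tibble: species, solvent, ec50_true, shape,
#'   hill).
#' @export
default_true_params <- function(shape = c("linear", "logistic"), hill = 2) {
  shape <- match.arg(shape)
  n <- 8L
  species <- sprintf("sp%02d", seq_len(n))
  mu0 <- seq(0.06, 0.7, length.out = n)
  sp <- tibble::tibble(species = species, mu0_true = mu0, lag_h = 2,
                       od0 = 0.02, od_max = 0.5)
  # per-solvent EC50 base for the fastest grower; slower growers scale down
  base <- c(PCE = 4, CT = 2, CF = 8, DCA = 20)
  rel <- 0.1 + 0.9 * (mu0 - min(mu0)) / (max(mu0) - min(mu0))
  ec <- tidyr::expand_grid(species = species, solvent = names(base))
  ec$ec50_true <- base[ec$solvent] * rel[match(ec$species, species)]
  ec$shape <- shape
  ec$hill <- hill
  list(species = sp, ec50 = ec)
}

#' Simulate one OD600 growth curve
#'
#' Deterministic curve plus optional read noise. The culture holds at the
#' inoculation OD through the lag, grows exponentially at
#' `mu0 * fraction`, and stops growing at the time the *control* culture
#' reaches its stationary OD -- solvent-stressed cultures start and cease
#' growth at the same times as controls and differ only in rate, ending
#' at a lower final OD.
#'
#' @param mu0 Solvent-free growth rate, 1/h.
#' @param fraction Fraction of mu0 retained under the tested
#'   concentration (see [dose_response_fraction()]).
#' @param times Sampling times in hours.
#' @param lag_h Lag duration, h.
#' @param od0 Inoculation OD.
#' @param od_max Stationary OD of the unstressed culture.
#' @param noise_sd SD of additive Gaussian noise; readings truncated
#'   at 0. Uses the current RNG state; seed via [simulate_assay()] or
#'   `set.seed()`.
#' @return An [od_series()].
#' @export
simulate_od_curve <- function(mu0, fraction, times, lag_h = 2, od0 = 0.02,
                              od_max = 0.5, noise_sd = 0) {
  if (!is_number(mu0) || mu0 <= 0) abort_input("mu0 must be positive")
  if (!is_number(fraction) || fraction < 0) {
    abort_input("fraction must be >= 0")
  }
  if (od_max <= od0 || od0 <= 0) {
    abort_input("need 0 < od0 < od_max")
  }
  t_stop <- lag_h + log(od_max / od0) / mu0  # control's growth-cessation time
  mu <- mu0 * fraction
  grow_t <- pmin(pmax(times - lag_h, 0), t_stop - lag_h)
  od <- pmin(od0 * exp(mu * grow_t), od_max)
  if (noise_sd > 0) {
    od <- pmax(0, od + stats::rnorm(length(od), 0, noise_sd))
  }
  od_series(times, od)
}

#' @keywords internal
#' @noRd
sampling_times <- function(mu0, lag_h, od0, od_max, n_times) {
  t_stop <- lag_h + log(od_max / od0) / mu0
  seq(0, t_stop * 1.25, length.out = n_times)
}

#' Simulate a full solvent-tolerance assay
#'
#' Generates the complete factorial dataset -- species x solvent x
#' (`n_conc` concentrations + shared no-solvent control) x replicates --
#' as OD600 time series in the long table dialect used by
#' [read_od_csv()], together with the ground-truth table for recovery
#' scoring. Dose series are geometric around each pair's true EC50 so
#' that the 50 percent point is bracketed; pass `conc_shift` to displace
#' them and study censoring.
#'
#' @param params Ground truth as from [default_true_params()].
#' @param config A [sim_config()]; its seed fully determines the output.
#' @param conc_shift Multiplier applied to every dose series (default 1).
#'   Values well above `conc_span` push the truth below the tested range
#'   (left censoring); values well below its inverse push it above
#'   (right censoring).
#' @return List with `od` (tibble: time_h, species, solvent, conc_mM,
#'   replicate, od600) and `truth` (list with `species` and `ec50`
#'   tibbles as in `params`, plus the tested concentrations).
#' @export
simulate_assay <- function(params, config, conc_shift = 1) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.list(params) || !all(c("species", "ec50") %in% names(params))) {
    abort_input("params must be a list with 'species' and 'ec50' tables")
  }
  sp <- params$species
  ec <- params$ec50

  out <- local_seed(config$seed, {
    rows <- vector("list", 0L)
    for (k in seq_len(nrow(sp))) {
      s <- sp[k, ]
      times <- sampling_times(s$mu0_true, s$lag_h, s$od0, s$od_max,
                              config$n_times)
      for (r in seq_len(config$replicates)) {
        cur <- simulate_od_curve(s$mu0_true, 1, times, s$lag_h, s$od0,
                                 s$od_max, config$noise_sd)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          time_h = times, species = s$species, solvent = "none",
          conc_mM = 0, replicate = r, od600 = cur$od)
      }
      ek <- ec[ec$species == s$species, ]
      for (m in seq_len(nrow(ek))) {
        e <- ek[m, ]
        concs <- dose_series(e$ec50_true, config$n_conc, config$conc_span) *
          conc_shift
        for (cc in concs) {
          frac <- dose_response_fraction(cc, e$ec50_true, e$shape, e$hill)
          for (r in seq_len(config$replicates)) {
            cur <- simulate_od_curve(s$mu0_true, frac, times, s$lag_h,
                                     s$od0, s$od_max, config$noise_sd)
            rows[[length(rows) + 1L]] <- tibble::tibble(
              time_h = times, species = s$species, solvent = e$solvent,
              conc_mM = cc, replicate = r, od600 = cur$od)
          }
        }
      }
    }
    dplyr::bind_rows(rows)
  })

  tested <- ec
  tested$conc_min <- tested$ec50_true / config$conc_span * conc_shift
  tested$conc_max <- tested$ec50_true * config$conc_span * conc_shift
  list(od = out, truth = list(species = sp, ec50 = tested))
}

# Evaluate code under a seed, restoring the caller's RNG state after.
#' @keywords internal
#' @noRd
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(),
                       inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
  }
  set.seed(seed)
  code
}
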