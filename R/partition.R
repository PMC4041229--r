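#' Describe a sealed assay vial
#'
#' Geometry and temperature of a sealed culture vial. The defaults match a
#' 25 mL Hungate tube holding 10 mL of medium, leaving 15 mL of headspace.
#'
#' @param liquid_ml Liquid (medium) volume in mL. Must be positive.
#' @param headspace_ml Headspace gas volume in mL. May be zero for the
#'   degenerate fully-liquid case.
#' @param temperature Incubation temperature in degrees Celsius, within
#'   0-60.
#' @return An object of class `vial_setup`.
#' @export
vial_setup <- function(liquid_ml = 10, headspace_ml = 15, temperature = 30) {
  if (!is_number(liquid_ml) || liquid_ml <= 0) {
    abort_input("liquid_ml must be positive")
  }
  if (!is_number(headspace_ml) || headspace_ml < 0) {
    abort_input("headspace_ml must be >= 0")
  }
  if (!is_number(temperature) || temperature < 0 || temperature > 60) {
    abort_input("temperature must be within 0-60 C")
  }
  structure(list(liquid_ml = liquid_ml, headspace_ml = headspace_ml,
                 temperature = temperature),
            class = "vial_setup")
}

#' Describe a solvent dose
#'
#' A dose is added either as the neat liquid (`mode = "neat"`) or as an
#' ethanolic stock solution (`mode = "ethanolic_stock"`, which requires
#' `stock_M`). The ethanol carrier itself is ignored in partitioning:
#' ethanol-only controls behave like no-solvent controls in this assay
#' design.
#'
#' @param volume_ul Volume added in microlitres. Must be positive.
#' @param mode `"neat"` or `"ethanolic_stock"`.
#' @param stock_M Stock concentration in mol/L (ethanolic stocks only).
#' @return An object of class `solvent_dose`.
#' @export
solvent_dose <- function(volume_ul, mode = c("neat", "ethanolic_stock"),
                         stock_M = NULL) {
  mode <- match.arg(mode)
  if (!is_number(volume_ul) || volume_ul <= 0) {
    abort_input("volume_ul must be positive")
  }
  if (mode == "ethanolic_stock") {
    if (is.null(stock_M) || !is_number(stock_M) || stock_M <= 0) {
      abort_input("stock_M (mol/L) must be positive for ethanolic_stock doses")
    }
  } else {
    stock_M <- NULL
  }
  structure(list(mode = mode, volume_ul = volume_ul, stock_M = stock_M),
            class = "solvent_dose")
}

#' Amount of solvent in a dose
#'
#' Converts a dose into micromoles: neat doses via the liquid density and
#' molar mass, stock doses via the stock concentration.
#'
#' @param dose A [solvent_dose()].
#' @param solvent A [solvent_spec()] (used for neat doses).
#' @return Amount in umol.
#' @examples
#' ct <- default_solvents()$CT
#' moles_added(solvent_dose(1, "neat"), ct)  # ~10.36 umol
#' @export
moles_added <- function(dose, solvent) {
  stopifnot(inherits(dose, "solvent_dose"), inherits(solvent, "solvent_spec"))
  if (dose$mode == "neat") {
    # uL * g/mL = mg; mg / (g/mol) = mmol/1000 -> umol
    dose$volume_ul * solvent$liquid_density / solvent$molar_mass * 1000
  } else {
    # uL * mol/L = umol
    dose$volume_ul * dose$stock_M
  }
}

#' Partition a solvent dose in a sealed vial
#'
#' Solves the closed-system two-phase equilibrium for a volatile solvent
#' dosed into a sealed vial. With total amount n (umol), liquid volume
#' V_aq and headspace V_gas (mL), and dimensionless Henry constant H_cc at
#' the vial temperature, the dissolved concentration is
#' \deqn{C_{aq} = n / (V_{aq} + H_{cc} V_{gas})}
#' in mmol/L. If this exceeds the solvent's aqueous solubility the aqueous
#' phase is capped at saturation, the headspace equilibrates with the
#' saturated solution, and the remaining amount is assigned to a separate
#' free (non-aqueous) phase. The nominal concentration -- total amount
#' over liquid volume, ignoring partitioning -- is always reported, as it
#' is the scale used for doses beyond the solubility limit.
#'
#' @param solvent A [solvent_spec()].
#' @param vial A [vial_setup()].
#' @param dose A [solvent_dose()], or a number taken directly as the total
#'   amount in umol.
#' @return An object of class `partition_result`: list with
#'   `total_umol`, `aqueous_mM`, `headspace_mM`, `nominal_mM`,
#'   `free_phase` (logical) and `free_phase_umol`.
#' @examples
#' pce <- default_solvents()$PCE
#' partition_dose(pce, vial_setup(10, 15, 30), solvent_dose(2, "neat"))
#' @export
partition_dose <- function(solvent, vial, dose) {
  stopifnot(inherits(solvent, "solvent_spec"), inherits(vial, "vial_setup"))
  n_total <- if (inherits(dose, "solvent_dose")) {
    moles_added(dose, solvent)
  } else if (is_number(dose) && dose > 0) {
    dose
  } else {
    abort_input("dose must be a solvent_dose or a positive amount in umol")
  }
  h <- henry_at_temperature(solvent, vial$temperature)
  v_aq <- vial$liquid_ml
  v_gas <- vial$headspace_ml
  sol <- solvent$aqueous_solubility

  c_aq <- n_total / (v_aq + h * v_gas)  # umol/mL == mmol/L
  if (c_aq > sol) {
    c_aq <- sol
    c_gas <- h * sol
    free <- n_total - c_aq * v_aq - c_gas * v_gas
  } else {
    c_gas <- h * c_aq
    free <- 0
  }
  structure(
    list(total_umol = n_total,
         aqueous_mM = c_aq,
         headspace_mM = c_gas,
         nominal_mM = n_total / v_aq,
         free_phase = free > 0,
         free_phase_umol = free),
    class = "partition_result"
  )
}

#' @export
print.partition_result <- function(x, ...) {
  cat(sprintf(
    "<partition_result> total %.4g umol: aqueous %.4g mM, headspace %.4g mM, nominal %.4g mM%s\n",
    x$total_umol, x$aqueous_mM, x$headspace_mM, x$nominal_mM,
    if (x$free_phase) sprintf(", free phase %.4g umol", x$free_phase_umol)
    else ""))
  invisible(x)
}

#' Plan a dose for a target dissolved concentration
#'
#' Inverse of [partition_dose()] below saturation: the total amount (umol)
#' that yields a desired dissolved concentration in a given vial.
#'
#' @param solvent A [solvent_spec()].
#' @param vial A [vial_setup()].
#' @param target_mM Desired aqueous concentration in mmol/L; must not
#'   exceed the solvent's aqueous solubility.
#' @return Total amount to add, in umol.
#' @export
dose_for_target_aqueous <- function(solvent, vial, target_mM) {
  stopifnot(inherits(solvent, "solvent_spec"), inherits(vial, "vial_setup"))
  if (!is_number(target_mM) || target_mM <= 0) {
    abort_input("target_mM must be positive")
  }
  if (target_mM > solvent$aqueous_solubility) {
    abort_input("target_mM exceeds the aqueous solubility of ", solvent$name,
                " (", solvent$aqueous_solubility, " mM)")
  }
  h <- henry_at_temperature(solvent, vial$temperature)
  target_mM * (vial$liquid_ml + h * vial$headspace_ml)
}
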