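#' Define a solvent's physicochemical constants
#'
#' A `solvent_spec` bundles the constants needed to partition a volatile
#' solvent between the aqueous phase and headspace of a sealed culture vial
#' and to interpret toxicity endpoints: molar mass, liquid density (for
#' neat-phase dosing), the octanol-water partition coefficient logarithm
#' (log Pow), the maximum aqueous solubility, and a temperature-indexed
#' table of dimensionless Henry constants (H_cc, gas-phase over
#' aqueous-phase concentration at equilibrium).
#'
#' @param name Character identifier, e.g. `"PCE"`.
#' @param molar_mass Molar mass in g/mol. Must be positive.
#' @param liquid_density Density of the neat liquid in g/mL. Must be
#'   positive.
#' @param log_pow Log10 octanol-water partition coefficient
#'   (dimensionless).
#' @param aqueous_solubility Maximum aqueous solubility in mmol/L. Must be
#'   positive.
#' @param henry_points Data frame with columns `temp_C` and `Hcc`: the
#'   dimensionless Henry constant at each temperature. At least one row;
#'   temperatures strictly increasing; all `Hcc` positive.
#'
#' @return An object of class `solvent_spec`.
#' @examples
#' ct <- solvent_spec("CT", 153.82, 1.594, 2.64, 5,
#'                    data.frame(temp_C = c(20, 30), Hcc = c(1.0, 1.46)))
#' henry_at_temperature(ct, 25)
#' @export
solvent_spec <- function(name, molar_mass, liquid_density, log_pow,
                         aqueous_solubility, henry_points) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    abort_input("solvent name must be a non-empty string")
  }
  for (fld in c("molar_mass", "liquid_density", "aqueous_solubility")) {
    v <- get(fld)
    if (!is_number(v) || v <= 0) {
      abort_input("solvent '", name, "': ", fld, " must be a positive number")
    }
  }
  if (!is_number(log_pow)) {
    abort_input("solvent '", name, "': log_pow must be a number")
  }
  hp <- as.data.frame(henry_points)
  if (!all(c("temp_C", "Hcc") %in% names(hp)) || nrow(hp) < 1L) {
    abort_input("solvent '", name,
                "': henry_points needs columns temp_C, Hcc and >= 1 row")
  }
  hp <- hp[order(hp$temp_C), c("temp_C", "Hcc"), drop = FALSE]
  if (anyDuplicated(hp$temp_C)) {
    abort_input("solvent '", name, "': henry_points temperatures must be distinct")
  }
  if (any(!is.finite(hp$Hcc)) || any(hp$Hcc <= 0)) {
    abort_input("solvent '", name, "': all Hcc values must be positive")
  }
  structure(
    list(name = name, molar_mass = molar_mass,
         liquid_density = liquid_density, log_pow = log_pow,
         aqueous_solubility = aqueous_solubility, henry_points = hp),
    class = "solvent_spec"
  )
}

#' @export
print.solvent_spec <- function(x, ...) {
  cat(sprintf(
    "<solvent_spec> %s: M = %.2f g/mol, rho = %.3f g/mL, log Pow = %.2f, S_aq = %.3g mM\n",
    x$name, x$molar_mass, x$liquid_density, x$log_pow, x$aqueous_solubility))
  cat(sprintf("  Henry H_cc at %s\n",
              paste(sprintf("%g C: %.3g", x$henry_points$temp_C,
                            x$henry_points$Hcc), collapse = ", ")))
  invisible(x)
}

#' Dimensionless Henry constant at a given temperature
#'
#' Looks up the Henry constant table of a solvent. Exact listed
#' temperatures return the table value. Between listed points, ln(H_cc) is
#' interpolated linearly against 1/T in kelvin (van't Hoff form). Queries
#' outside the tabulated range are clamped to the nearest endpoint with a
#' warning, since assay temperatures vary by a few degrees between species.
#'
#' @param solvent A [solvent_spec()].
#' @param temperature Temperature in degrees Celsius.
#' @return The dimensionless Henry constant H_cc (gas/aqueous
#'   concentration ratio).
#' @export
henry_at_temperature <- function(solvent, temperature) {
  stopifnot(inherits(solvent, "solvent_spec"))
  if (!is_number(temperature)) {
    abort_input("temperature must be a single finite number")
  }
  hp <- solvent$henry_points
  hit <- which(abs(hp$temp_C - temperature) < 1e-9)
  if (length(hit) == 1L) {
    return(hp$Hcc[hit])
  }
  if (temperature < hp$temp_C[1L]) {
    warning(sprintf(
      "%s: %g C is below the Henry table range (%g-%g C); using value at %g C",
      solvent$name, temperature, hp$temp_C[1L], hp$temp_C[nrow(hp)],
      hp$temp_C[1L]), call. = FALSE)
    return(hp$Hcc[1L])
  }
  if (temperature > hp$temp_C[nrow(hp)]) {
    warning(sprintf(
      "%s: %g C is above the Henry table range (%g-%g C); using value at %g C",
      solvent$name, temperature, hp$temp_C[1L], hp$temp_C[nrow(hp)],
      hp$temp_C[nrow(hp)]), call. = FALSE)
    return(hp$Hcc[nrow(hp)])
  }
  # van't Hoff interpolation: ln(H) linear in 1/T(K)
  invT <- 1 / (hp$temp_C + 273.15)
  q <- 1 / (temperature + 273.15)
  i <- findInterval(temperature, hp$temp_C)
  w <- (q - invT[i]) / (invT[i + 1L] - invT[i])
  exp((1 - w) * log(hp$Hcc[i]) + w * log(hp$Hcc[i + 1L]))
}

#' Read solvent constants from a YAML file
#'
#' The file holds one mapping per solvent with keys `molar_mass_g_mol`,
#' `density_g_ml`, `log_pow`, `solubility_mM` and `henry`, the latter a
#' list of `[temp_C, Hcc]` pairs. See
#' `system.file("extdata", "solvents.yaml", package = "soltol")` for the
#' shipped defaults.
#'
#' @param path Path to the YAML file.
#' @return Named list of [solvent_spec()] objects.
#' @export
read_solvents_yaml <- function(path) {
  if (!file.exists(path)) {
    abort_input("solvent constants file not found: ", path)
  }
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(nm) {
    s <- raw[[nm]]
    need <- c("molar_mass_g_mol", "density_g_ml", "log_pow", "solubility_mM",
              "henry")
    miss <- setdiff(need, names(s))
    if (length(miss)) {
      abort_input("solvent '", nm, "': missing keys: ",
                  paste(miss, collapse = ", "))
    }
    hp <- do.call(rbind, lapply(s$henry, function(p) {
      if (length(p) != 2L) {
        abort_input("solvent '", nm, "': henry entries must be [temp_C, Hcc]")
      }
      data.frame(temp_C = p[[1L]], Hcc = p[[2L]])
    }))
    solvent_spec(nm, s$molar_mass_g_mol, s$density_g_ml, s$log_pow,
                 s$solubility_mM, hp)
  })
  names(out) <- names(raw)
  out
}

#' Default constants for the four chlorinated solvents
#'
#' Returns specs for perchloroethene (PCE), carbon tetrachloride (CT),
#' chloroform (CF) and 1,2-dichloroethane (DCA), read from the constants
#' file shipped with the package. Henry constants and the CF and DCA
#' solubilities are implementer-sourced literature values (the file
#' comments carry provenance notes); edit a copy of the file to substitute
#' your own.
#'
#' @return Named list of [solvent_spec()] objects with names
#'   `PCE`, `CT`, `CF`, `DCA`.
#' @export
default_solvents <- function() {
  read_solvents_yaml(system.file("extdata", "solvents.yaml",
                                 package = "soltol", mustWork = TRUE))
}
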