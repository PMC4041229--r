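test_that("Henry constant lookup, van't Hoff interpolation and clamping", {
  one <- solvent_spec("one", 100, 1, 2, 100,
                      data.frame(temp_C = 30, Hcc = 0.2))
  expect_identical(henry_at_temperature(one, 30), 0.2)

  two <- solvent_spec("two", 100, 1, 2, 100,
                      data.frame(temp_C = c(20, 40), Hcc = c(0.1, 0.4)))
  # frozen from the two-point ln(H) vs 1/T(K) closed form, computed
  # independently of the implementation
  expect_equal(henry_at_temperature(two, 30), 0.2046256458,
               tolerance = 1e-9)
  expect_identical(henry_at_temperature(two, 20), 0.1)

  expect_warning(h <- henry_at_temperature(two, 10), "below the Henry")
  expect_identical(h, 0.1)
  expect_warning(h <- henry_at_temperature(two, 50), "above the Henry")
  expect_identical(h, 0.4)
})

test_that("solvent_spec validates its invariants", {
  hp <- data.frame(temp_C = 30, Hcc = 0.2)
  expect_error(solvent_spec("x", -1, 1, 2, 1, hp), "molar_mass")
  expect_error(solvent_spec("x", 100, 1, 2, 1,
                            data.frame(temp_C = c(30, 30),
                                       Hcc = c(0.2, 0.3))),
               "distinct")
  expect_error(solvent_spec("x", 100, 1, 2, 1,
                            data.frame(temp_C = 30, Hcc = -0.2)),
               "positive")
  expect_error(solvent_spec("x", 100, 1, 2, 1, hp[0, ]), "1 row")
})

test_that("dose amounts convert correctly to micromoles", {
  ct <- default_solvents()$CT
  # hand unit conversion: 1 uL * 1.594 g/mL / 153.82 g/mol = 10.3628 umol
  expect_equal(moles_added(solvent_dose(1, "neat"), ct), 10.362762,
               tolerance = 1e-6)
  expect_equal(moles_added(solvent_dose(100, "ethanolic_stock",
                                        stock_M = 0.1), ct), 10)
  expect_error(solvent_dose(0, "ethanolic_stock", stock_M = 0.1),
               "positive")
  expect_error(solvent_dose(10, "ethanolic_stock"), "stock_M")
})

test_that("partition_dose solves the two-phase closed-vial equilibrium", {
  sv <- solvent_spec("x", 100, 1, 2, 1e6,
                     data.frame(temp_C = 30, Hcc = 0.2))
  p <- partition_dose(sv, vial_setup(10, 15, 30), 10)
  # mass-balance oracle: n = C_aq * V_aq + Hcc * C_aq * V_gas
  expect_equal(p$aqueous_mM, 0.76923077, tolerance = 1e-7)
  expect_equal(p$headspace_mM, 0.2 * p$aqueous_mM)
  expect_false(p$free_phase)
  expect_equal(p$nominal_mM, 1)

  # no headspace: dissolved equals nominal
  p0 <- partition_dose(sv, vial_setup(10, 0, 30), 10)
  expect_equal(p0$aqueous_mM, p0$nominal_mM)

  # involatile limit: tiny Henry constant gives nominal concentration
  tiny <- solvent_spec("tiny", 100, 1, 2, 1e6,
                       data.frame(temp_C = 30, Hcc = 1e-12))
  expect_equal(partition_dose(tiny, vial_setup(10, 15, 30), 10)$aqueous_mM,
               1, tolerance = 1e-9)
})

test_that("doses beyond solubility saturate the aqueous phase", {
  pce_like <- solvent_spec("pce", 165.83, 1.622, 2.88, 0.9,
                           data.frame(temp_C = 30, Hcc = 0.9))
  v <- vial_setup(10, 15, 30)
  # choose n so the unconstrained aqueous concentration would be 2.0 mM
  n <- 2.0 * (10 + 0.9 * 15)
  p <- partition_dose(pce_like, v, n)
  expect_equal(p$aqueous_mM, 0.9)
  expect_true(p$free_phase)
  expect_gt(p$nominal_mM, 0.9)
  expect_equal(p$headspace_mM, 0.9 * 0.9)
  mass <- p$aqueous_mM * 10 + p$headspace_mM * 15 + p$free_phase_umol
  expect_equal(mass, p$total_umol, tolerance = 1e-12)
})

test_that("mass balance holds and aqueous concentration is monotone", {
  set.seed(42)
  for (i in 1:200) {
    h <- stats::runif(1, 0.01, 3)
    sol <- stats::runif(1, 0.5, 50)
    sv <- solvent_spec("r", 100, 1.5, 2, sol,
                       data.frame(temp_C = 30, Hcc = h))
    v <- vial_setup(stats::runif(1, 2, 50), stats::runif(1, 0, 50), 30)
    n <- stats::runif(1, 0.1, 500)
    p <- partition_dose(sv, v, n)
    mass <- p$aqueous_mM * v$liquid_ml + p$headspace_mM * v$headspace_ml +
      p$free_phase_umol
    expect_equal(mass, n, tolerance = 1e-9)
    expect_lte(p$aqueous_mM, sol * (1 + 1e-12))
    expect_identical(p$free_phase, p$free_phase_umol > 0)
  }

  # below solubility, C_aq strictly decreases in Hcc and headspace volume
  base <- function(h, vg) {
    sv <- solvent_spec("m", 100, 1.5, 2, 1e6,
                       data.frame(temp_C = 30, Hcc = h))
    partition_dose(sv, vial_setup(10, vg, 30), 10)$aqueous_mM
  }
  expect_true(all(diff(sapply(c(0.1, 0.5, 1, 2), base, vg = 15)) < 0))
  expect_true(all(diff(sapply(c(0, 5, 15, 40), function(vg)
    base(0.5, vg))) < 0))
})

test_that("planned doses round-trip through the partition model", {
  sv <- default_solvents()$CF
  v <- vial_setup(10, 15, 25)
  for (target in c(0.05, 1, 10, 60)) {
    n <- dose_for_target_aqueous(sv, v, target)
    expect_equal(partition_dose(sv, v, n)$aqueous_mM, target,
                 tolerance = 1e-9)
  }
  expect_error(dose_for_target_aqueous(sv, v, 100), "solubility")
})

test_that("shipped solvent constants load and are self-consistent", {
  sv <- default_solvents()
  expect_setequal(names(sv), c("PCE", "CT", "CF", "DCA"))
  expect_equal(sv$PCE$aqueous_solubility, 0.9)
  expect_equal(sv$CT$aqueous_solubility, 5)
  lp <- vapply(sv[c("DCA", "CF", "CT", "PCE")], function(s) s$log_pow,
               numeric(1))
  expect_true(all(diff(lp) > 0))  # hydrophobicity order DCA < CF < CT < PCE
})
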