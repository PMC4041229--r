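sv <- default_solvents()

test_that("percent of solubility handles points and censored records", {
  expect_equal(percent_of_solubility(1, sv$CT)$percent, 20)
  expect_equal(percent_of_solubility(sv$CT$aqueous_solubility, sv$CT)$percent,
               100)
  expect_equal(percent_of_solubility(0.45, sv$PCE)$percent, 50)

  right <- list(ec50_mM = NA, censoring = "right", bound_mM = 2.5)
  p <- percent_of_solubility(right, sv$CT)
  expect_identical(p$comparator, ">")
  expect_equal(p$percent, 50)
  left <- list(ec50_mM = NA, censoring = "left", bound_mM = 0.5)
  expect_identical(percent_of_solubility(left, sv$CT)$comparator, "<")
})

test_that("free-phase tolerance requires the EC50 to exceed solubility", {
  expect_true(classify_free_phase_tolerance(4.95, sv$PCE))
  expect_false(classify_free_phase_tolerance(
    list(ec50_mM = NA, censoring = "left", bound_mM = 0.2), sv$PCE))
  # point estimate exactly at solubility: strict inequality
  expect_false(classify_free_phase_tolerance(0.9, sv$PCE))
  # right-censored at the solubility: the true EC50 lies strictly above
  expect_true(classify_free_phase_tolerance(
    list(ec50_mM = NA, censoring = "right", bound_mM = 0.9), sv$PCE))
  # classification agrees with percent-of-solubility > 100 for points
  for (v in c(0.3, 0.9, 1.5)) {
    expect_identical(classify_free_phase_tolerance(v, sv$PCE),
                     percent_of_solubility(v, sv$PCE)$percent > 100)
  }
})

make_panel <- function(values, mu0 = NULL) {
  rows <- do.call(rbind, lapply(names(values), function(sp) {
    data.frame(species = sp, solvent = names(values[[sp]]),
               ec50_mM = as.numeric(values[[sp]]), censoring = "point",
               bound_mM = NA_real_, stringsAsFactors = FALSE)
  }))
  species_panel(rows, mu0, sv)
}

test_that("normalized tolerance scores reproduce hand-computed ratios", {
  pan <- make_panel(list(
    A = c(PCE = 4, CT = 2, CF = 8, DCA = 20),
    B = c(PCE = 2, CT = 1, CF = 4, DCA = 10),
    C = c(PCE = 1, CT = 0.5, CF = 2, DCA = 5)))
  sc <- normalized_tolerance_scores(pan, reference = "A")
  su <- sc$summary
  expect_equal(su$avg_score[su$species == "A"], 100)
  expect_equal(su$avg_score[su$species == "B"], 50)
  expect_equal(su$avg_score[su$species == "C"], 25)

  # "max" reference coincides with species A here
  sc2 <- normalized_tolerance_scores(pan, reference = "max")
  expect_equal(sc2$summary$avg_score, su$avg_score)

  # invariance: rescaling all EC50s of one solvent leaves scores unchanged
  pan2 <- make_panel(list(
    A = c(PCE = 4, CT = 2 * 10, CF = 8, DCA = 20),
    B = c(PCE = 2, CT = 1 * 10, CF = 4, DCA = 10),
    C = c(PCE = 1, CT = 0.5 * 10, CF = 2, DCA = 5)))
  sc3 <- normalized_tolerance_scores(pan2, reference = "A")
  expect_equal(sc3$summary$avg_score, su$avg_score)

  # monotonicity: raising one EC50 never lowers that species' average
  pan3 <- make_panel(list(
    A = c(PCE = 4, CT = 2, CF = 8, DCA = 20),
    B = c(PCE = 2, CT = 1.5, CF = 4, DCA = 10),
    C = c(PCE = 1, CT = 0.5, CF = 2, DCA = 5)))
  su3 <- normalized_tolerance_scores(pan3, reference = "A")$summary
  expect_gte(su3$avg_score[su3$species == "B"],
             su$avg_score[su$species == "B"])
})

test_that("EC50 vs mu0 regression recovers exact and simulated slopes", {
  mu0 <- data.frame(species = c("A", "B", "C", "D"),
                    mu0 = c(0.1, 0.3, 0.5, 0.7))
  exact <- make_panel(list(
    A = c(PCE = 1.2), B = c(PCE = 2.6), C = c(PCE = 4.0),
    D = c(PCE = 5.4)), mu0)
  r <- regress_ec50_vs_mu0(exact)
  expect_equal(r$r2, 1, tolerance = 1e-12)
  expect_equal(r$slope, 7, tolerance = 1e-9)

  # noisy generating model: recovered slope within 2 SE of truth (lm as
  # the independent route)
  set.seed(11)
  n <- 12
  mu <- stats::runif(n, 0.05, 0.8)
  a <- 6; b <- 0.5
  y <- a * mu + b + stats::rnorm(n, 0, 0.4)
  vals <- stats::setNames(lapply(seq_len(n), function(i) c(PCE = y[i])),
                          paste0("s", seq_len(n)))
  pan <- make_panel(vals, data.frame(species = paste0("s", seq_len(n)),
                                     mu0 = mu))
  r2 <- regress_ec50_vs_mu0(pan)
  se <- summary(stats::lm(y ~ mu))$coefficients["mu", "Std. Error"]
  expect_lt(abs(r2$slope - a), 2 * se)
  expect_equal(r2$slope, unname(stats::coef(stats::lm(y ~ mu))[2]),
               tolerance = 1e-9)

  two <- make_panel(list(A = c(PCE = 1), B = c(PCE = 2)),
                    data.frame(species = c("A", "B"), mu0 = c(0.1, 0.2)))
  expect_error(regress_ec50_vs_mu0(two), ">= 3")
})

test_that("toxicity ranking flags violations of the log Pow order", {
  ok <- make_panel(list(A = c(PCE = 0.9, CT = 1.5, CF = 4, DCA = 12)))
  expect_equal(nrow(toxicity_ranking(ok)$violations), 0)

  # CT more toxic than PCE despite its lower log Pow: one violation
  inv <- make_panel(list(A = c(PCE = 1.5, CT = 0.9, CF = 4, DCA = 12)))
  v <- toxicity_ranking(inv)$violations
  expect_equal(nrow(v), 1)
  expect_identical(v$more_toxic, "CT")
  expect_identical(v$less_toxic, "PCE")
})

test_that("curated results fixture matches the published statements", {
  cur <- load_curated_results()
  expect_equal(nrow(cur), 32)  # 8 species x 4 solvents
  expect_equal(length(unique(cur$species)), 8)
  expect_setequal(unique(cur$solvent), c("PCE", "CT", "CF", "DCA"))
  expect_true(all(nzchar(cur$source_note)))

  # the only numeric point values are those printed in the text
  pts <- cur[cur$censoring == "point", ]
  expect_setequal(round(pts$ec50_mM, 2), c(4.95, 2.4, 0.2, 6.5))

  # five of eight species tolerated free-phase PCE
  pce <- cur[cur$solvent == "PCE", ]
  tol <- vapply(seq_len(nrow(pce)), function(i)
    classify_free_phase_tolerance(pce[i, ], sv$PCE), logical(1))
  expect_equal(sum(tol), 5)
  expect_identical(tol, pce$above_pce_solubility)

  # the three CT-intolerant respirers are left-censored at 80/80/30 uM
  ct_left <- cur[cur$solvent == "CT" & cur$censoring == "left", ]
  expect_setequal(ct_left$bound_mM, c(0.08, 0.08, 0.03))
  expect_true(all(ct_left$no_growth_at_lowest))

  # 1,2-DCA was tolerated at >= 6.5 mM by every species
  dca <- cur[cur$solvent == "DCA", ]
  dca_rep <- ifelse(dca$censoring == "point", dca$ec50_mM, dca$bound_mM)
  expect_true(all(dca_rep >= 6.5))

  # CF stayed above 3.5 mM for six species
  cf <- cur[cur$solvent == "CF", ]
  expect_equal(sum(cf$censoring == "right" & cf$bound_mM == 3.5), 6)
})

test_that("curated records classify and rank consistently", {
  cur <- load_curated_results()
  pan <- species_panel(cur, NULL, sv)
  rk <- toxicity_ranking(pan)

  # G. sulfurreducens has usable records for all four solvents:
  # CT most toxic, then CF, then PCE, then DCA
  g <- rk$ranking[rk$ranking$species == "G. sulfurreducens", ]
  expect_identical(g$solvent, c("CT", "CF", "PCE", "DCA"))

  # 1,2-DCA is the least toxic solvent for every species
  least <- dplyr::slice_max(dplyr::group_by(rk$ranking, species),
                            order_by = rank, n = 1)
  expect_true(all(least$solvent == "DCA"))

  # Klebsiella/PCE, Paenibacillus/CT, G. sulfurreducens/CF resolve
  kp <- cur[cur$species == "Klebsiella sp." & cur$solvent == "PCE", ]
  expect_equal(kp$ec50_mM, 4.95)
  expect_identical(kp$method, "extrapolated")
  expect_equal(cur$ec50_mM[cur$species == "Paenibacillus sp." &
                             cur$solvent == "CT"], 2.4)
  expect_equal(cur$ec50_mM[cur$species == "G. sulfurreducens" &
                             cur$solvent == "CF"], 0.2)
})
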