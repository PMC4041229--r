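test_that("OD tables round-trip through CSV losslessly", {
  sim <- simulate_assay(small_params(), sim_config(seed = 21))
  path <- withr::local_tempfile(fileext = ".csv")
  write_od_csv(sim$od, path)
  back <- read_od_csv(path)
  expect_equal(as.data.frame(back[, names(sim$od)]),
               as.data.frame(sim$od[do.call(order, sim$od[c(
                 "species", "solvent", "conc_mM", "replicate",
                 "time_h")]), ]),
               ignore_attr = TRUE)
})

test_that("dose columns resolve through the partition model", {
  sv <- default_solvents()
  df <- data.frame(
    time_h = rep(0:3, 2), species = "spA",
    solvent = rep(c("CT", "CT"), each = 4),
    replicate = 1, mode = "neat", volume_ul = rep(c(1, 2), each = 4),
    od600 = rep(0.05 * exp(0.4 * (0:3)), 2))
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  od <- read_od_csv(path, solvents = sv, vial = vial_setup(10, 15, 30))
  p1 <- partition_dose(sv$CT, vial_setup(10, 15, 30),
                       solvent_dose(1, "neat"))
  expect_equal(sort(unique(od$conc_mM))[1], p1$aqueous_mM)
  expect_identical(unique(od$conc_scale), "aqueous")
})

test_that("malformed OD files give descriptive errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  base <- data.frame(time_h = 0:2, species = "a", solvent = "none",
                     conc_mM = 0, replicate = 1,
                     od600 = c(0.1, 0.2, 0.3))

  no_col <- base[, setdiff(names(base), "od600")]
  utils::write.csv(no_col, path, row.names = FALSE)
  expect_error(read_od_csv(path), "od600")

  dup <- rbind(base, base[2, ])
  utils::write.csv(dup, path, row.names = FALSE)
  expect_error(read_od_csv(path), "duplicated")

  mixed <- base
  mixed$mode <- "neat"
  mixed$volume_ul <- 1
  utils::write.csv(mixed, path, row.names = FALSE)
  expect_error(read_od_csv(path), "mixed")
})

test_that("blank rows are averaged per time point and subtracted", {
  df <- data.frame(
    time_h = rep(0:2, 3), species = "a", solvent = "none", conc_mM = 0,
    replicate = rep(c(1, 91, 92), each = 3),
    od600 = c(0.15, 0.25, 0.35, 0.04, 0.04, 0.06, 0.06, 0.06, 0.04),
    is_blank = rep(c(FALSE, TRUE, TRUE), each = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  od <- read_od_csv(path)
  expect_equal(od$od600, c(0.15, 0.25, 0.35) - 0.05)
})

test_that("run_report chains the pipeline and logs decisions", {
  sim <- simulate_assay(small_params(), sim_config(seed = 7))
  out <- withr::local_tempdir()
  rep1 <- run_report(sim$od, out_dir = out)

  expect_equal(nrow(rep1$ec50), 3 * 4)  # species x solvent rows
  expect_true(all(file.exists(file.path(out, c(
    "growthrates.csv", "ec50.csv", "report.json")))))

  # re-running the same seeded dataset reproduces the report exactly
  rep2 <- run_report(simulate_assay(small_params(),
                                    sim_config(seed = 7))$od)
  expect_identical(rep1$ec50, rep2$ec50)
  expect_identical(rep1$log, rep2$log)

  # solubility analytics carried per pair with known constants
  expect_equal(nrow(rep1$solubility), nrow(rep1$ec50))
  expect_true(is.numeric(rep1$scores$summary$avg_score))
})

test_that("a condition with no growth at the lowest dose is left-censored", {
  p <- small_params()
  sim <- simulate_assay(p, sim_config(noise_sd = 0, seed = 13))
  od <- sim$od
  # flatten the lowest-dose cultures of one pair at the inoculation OD
  pair <- p$ec50[1, ]
  sel <- od$species == pair$species & od$solvent == pair$solvent
  low <- min(od$conc_mM[sel])
  od$od600[sel & od$conc_mM == low] <- 0.02
  rep <- run_report(od)
  row <- rep$ec50[rep$ec50$species == pair$species &
                    rep$ec50$solvent == pair$solvent, ]
  expect_identical(row$censoring, "left")
  expect_equal(row$bound_mM, low)
  expect_match(paste(rep$log, collapse = "\n"), "censored EC50")
  expect_match(paste(rep$log, collapse = "\n"), "zero growth assigned")
})
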