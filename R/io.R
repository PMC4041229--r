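#' Read an OD600 assay table
#'
#' Reads the long CSV dialect used throughout the package: one row per
#' reading with columns `time_h`, `species`, `solvent`, `replicate`,
#' `od600`, and either `conc_mM` (dissolved or nominal concentration) or
#' the dose columns `mode` (`"neat"`/`"ethanolic_stock"`), `volume_ul`
#' and `stock_M`, which are resolved to concentrations through the
#' closed-vial partition model. An optional logical `is_blank` column
#' marks medium blanks, which are averaged per species and time point and
#' subtracted from the readings.
#'
#' No-solvent controls are rows with `conc_mM == 0` (conventionally with
#' `solvent = "none"`).
#'
#' @param path CSV file path.
#' @param solvents Named list of [solvent_spec()], required when dose
#'   columns are used.
#' @param vial A [vial_setup()] used for dose resolution (default 10 mL
#'   medium, 15 mL headspace).
#' @param temperatures Optional named vector of per-species incubation
#'   temperatures (deg C) overriding the vial temperature during dose
#'   resolution.
#' @return Tibble with columns `time_h`, `species`, `solvent`, `conc_mM`,
#'   `replicate`, `od600` (blank-corrected), sorted by condition and
#'   time. When doses were resolved, also `conc_scale` (`"aqueous"` or
#'   `"nominal"`, the latter when a free phase formed).
#' @export
read_od_csv <- function(path, solvents = NULL, vial = vial_setup(),
                        temperatures = NULL) {
  if (!file.exists(path)) {
    abort_input("OD file not found: ", path)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  raw$.row <- seq_len(nrow(raw)) + 1L  # header is line 1

  need <- c("time_h", "species", "solvent", "replicate", "od600")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    abort_input("missing required columns: ", paste(miss, collapse = ", "))
  }
  has_conc <- "conc_mM" %in% names(raw)
  has_dose <- all(c("mode", "volume_ul") %in% names(raw))
  if (has_conc && has_dose) {
    abort_input("mixed specification: provide either conc_mM or dose ",
                "columns (mode, volume_ul, stock_M), not both")
  }
  if (!has_conc && !has_dose) {
    abort_input("need either a conc_mM column or dose columns ",
                "(mode, volume_ul, stock_M)")
  }

  blanks <- NULL
  if ("is_blank" %in% names(raw)) {
    isb <- as.logical(raw$is_blank)
    isb[is.na(isb)] <- FALSE
    blanks <- raw[isb, ]
    raw <- raw[!isb, ]
  }

  if (has_dose) {
    if (is.null(solvents)) {
      abort_input("dose columns present: 'solvents' specs are required")
    }
    raw$conc_mM <- NA_real_
    raw$conc_scale <- NA_character_
    key <- paste(raw$species, raw$solvent, raw$mode, raw$volume_ul,
                 if ("stock_M" %in% names(raw)) raw$stock_M else "")
    for (k in unique(key)) {
      i <- which(key == k)
      r1 <- raw[i[1L], ]
      if (is.na(r1$volume_ul) || r1$volume_ul == 0) {
        raw$conc_mM[i] <- 0
        raw$conc_scale[i] <- "aqueous"
        next
      }
      sv <- solvents[[r1$solvent]]
      if (is.null(sv)) {
        abort_input("row ", r1$.row, ": no solvent_spec for '", r1$solvent,
                    "'")
      }
      v <- vial
      if (!is.null(temperatures) && r1$species %in% names(temperatures)) {
        v <- vial_setup(vial$liquid_ml, vial$headspace_ml,
                        temperatures[[r1$species]])
      }
      d <- solvent_dose(r1$volume_ul, r1$mode,
                        stock_M = if ("stock_M" %in% names(raw))
                          r1$stock_M else NULL)
      p <- partition_dose(sv, v, d)
      raw$conc_mM[i] <- if (p$free_phase) p$nominal_mM else p$aqueous_mM
      raw$conc_scale[i] <- if (p$free_phase) "nominal" else "aqueous"
    }
  }

  raw$time_h <- as.numeric(raw$time_h)
  raw$od600 <- as.numeric(raw$od600)
  raw$conc_mM <- as.numeric(raw$conc_mM)
  bad <- raw$.row[!is.finite(raw$time_h) | !is.finite(raw$od600) |
                    !is.finite(raw$conc_mM)]
  if (length(bad)) {
    abort_input("non-numeric time_h/od600/conc_mM at row(s): ",
                paste(utils::head(bad, 5L), collapse = ", "))
  }

  if (!is.null(blanks) && nrow(blanks) > 0) {
    bl <- stats::aggregate(od600 ~ species + time_h, data = blanks, mean)
    names(bl)[names(bl) == "od600"] <- ".blank"
    raw <- merge(raw, bl, by = c("species", "time_h"), all.x = TRUE,
                 sort = FALSE)
    raw$.blank[is.na(raw$.blank)] <- 0
    raw$od600 <- raw$od600 - raw$.blank
    raw$.blank <- NULL
  }

  key <- paste(raw$species, raw$solvent, raw$conc_mM, raw$replicate,
               sep = "\r")
  dup <- duplicated(paste(key, raw$time_h, sep = "\r"))
  if (any(dup)) {
    abort_input("duplicated (condition, time) reading at row(s): ",
                paste(utils::head(raw$.row[dup], 5L), collapse = ", "))
  }

  keep <- c("time_h", "species", "solvent", "conc_mM", "replicate", "od600",
            if (has_dose) "conc_scale")
  out <- tibble::as_tibble(raw[order(raw$species, raw$solvent, raw$conc_mM,
                                     raw$replicate, raw$time_h), keep])
  out
}

#' Write an OD600 assay table
#'
#' @param od Tibble as produced by [read_od_csv()] or
#'   [simulate_assay()]`$od`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_od_csv <- function(od, path) {
  utils::write.csv(as.data.frame(od), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Fit growth rates for every culture in an assay table
#'
#' Applies [fit_growth_rate()] to each (species, solvent, concentration,
#' replicate) series.
#'
#' By default the exponential window is detected once per species, on its
#' no-solvent control replicates, and shared with every treated culture
#' of that species (`share_window = TRUE`). In this assay design cultures
#' of a species start and stop growing together and differ only in rate,
#' so the high-signal controls pin down the window far more reliably than
#' a weakly growing, strongly inhibited culture can -- per-series
#' detection on such low-amplitude curves either fails the linearity
#' filter outright or locks onto read noise. The shared window is the
#' median of the per-control-replicate windows. Species without usable
#' controls fall back to per-series detection, as does
#' `share_window = FALSE`.
#'
#' @param od Long OD tibble (see [read_od_csv()]).
#' @param min_points,r2_min Window-detection settings, see
#'   [detect_exponential_window()].
#' @param share_window Detect the window on each species' controls and
#'   reuse it for that species' treated cultures (default `TRUE`).
#' @return Tibble with one row per culture: condition key plus `mu`,
#'   `zero_growth`, `t_start`, `t_end`, `n_points`, `r2`, `max_od`.
#' @export
fit_growth_table <- function(od, min_points = 5L, r2_min = 0.99,
                             share_window = TRUE) {
  shared <- list()
  if (isTRUE(share_window)) {
    ctrl <- od[od$conc_mM == 0, ]
    ckey <- paste(ctrl$species, ctrl$replicate, sep = "\r")
    wins <- lapply(split(seq_len(nrow(ctrl)), ckey), function(i) {
      i <- i[order(ctrl$time_h[i])]
      detect_exponential_window(od_series(ctrl$time_h[i], ctrl$od600[i]),
                                min_points = min_points, r2_min = r2_min)
    })
    for (sp in unique(ctrl$species)) {
      w <- wins[vapply(strsplit(names(wins), "\r"),
                       function(p) p[1L] == sp, logical(1))]
      w <- w[!vapply(w, is.null, logical(1))]
      if (length(w)) {
        shared[[sp]] <- c(
          stats::median(vapply(w, function(x) x$t_start, numeric(1))),
          stats::median(vapply(w, function(x) x$t_end, numeric(1))))
      }
    }
  }

  key <- paste(od$species, od$solvent, od$conc_mM, od$replicate, sep = "\r")
  idx <- split(seq_len(nrow(od)), key)
  rows <- lapply(idx, function(i) {
    i <- i[order(od$time_h[i])]
    sp <- od$species[i[1L]]
    fit <- fit_growth_rate(od_series(od$time_h[i], od$od600[i]),
                           window = shared[[sp]],
                           min_points = min_points, r2_min = r2_min)
    tibble::tibble(
      species = sp, solvent = od$solvent[i[1L]],
      conc_mM = od$conc_mM[i[1L]], replicate = od$replicate[i[1L]],
      mu = fit$mu, zero_growth = fit$zero_growth, t_start = fit$t_start,
      t_end = fit$t_end, n_points = fit$n_points, r2 = fit$r2,
      max_od = fit$max_od)
  })
  out <- dplyr::bind_rows(rows)
  out[order(out$species, out$solvent, out$conc_mM, out$replicate), ]
}

#' Express treated growth as percent of the no-solvent control
#'
#' Computes each species' control mean mu0 from the `conc_mM == 0` rows
#' and expresses every treated replicate's growth rate as a percentage
#' of it.
#'
#' @param fits Growth-rate table from [fit_growth_table()].
#' @return List with `relative` (treated rows plus `percent`) and `mu0`
#'   (tibble: species, mu0, n_controls).
#' @export
relative_growth_table <- function(fits) {
  ctrl <- fits[fits$conc_mM == 0, ]
  if (nrow(ctrl) == 0) {
    abort_input("no control rows (conc_mM == 0) found")
  }
  mu0 <- ctrl |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(mu0 = mean(.data$mu), n_controls = dplyr::n(),
                     .groups = "drop")
  dead <- mu0$species[mu0$mu0 <= 0]
  if (length(dead)) {
    abort_input("all no-solvent controls show zero growth for: ",
                paste(dead, collapse = ", "))
  }
  treated <- fits[fits$conc_mM > 0, ]
  treated <- dplyr::left_join(treated, mu0[, c("species", "mu0")],
                              by = "species")
  treated$percent <- 100 * treated$mu / treated$mu0
  list(relative = tibble::as_tibble(treated), mu0 = mu0)
}

#' Estimate EC50s for every species-solvent pair
#'
#' Builds one dose-response curve per replicate (replicate r at every
#' concentration of the series) and summarizes them with
#' [ec50_replicate_stats()].
#'
#' @param relative Output of [relative_growth_table()] (the list, or its
#'   `relative` tibble).
#' @param mode `"replicate"` or `"average"`, see [ec50_replicate_stats()].
#' @param scale Concentration-scale label carried into the estimates.
#' @param ... Passed to [estimate_ec50()].
#' @return Tibble: `species`, `solvent`, `ec50_mM`, `censoring`,
#'   `bound_mM`, `method`, `sd_mM`, `n_reps`, `scale`, `diagnostics`.
#' @export
estimate_ec50_table <- function(relative, mode = "replicate",
                                scale = "aqueous", ...) {
  rel <- if (is.list(relative) && !is.data.frame(relative))
    relative$relative else relative
  key <- paste(rel$species, rel$solvent, sep = "\r")
  rows <- lapply(unique(key), function(k) {
    sub <- rel[key == k, ]
    curves <- lapply(unique(sub$replicate), function(r) {
      s <- sub[sub$replicate == r, ]
      s <- s[order(s$conc_mM), ]
      list(conc = s$conc_mM, percent = s$percent)
    })
    est <- ec50_replicate_stats(curves, mode = mode, ...)
    tibble::tibble(
      species = sub$species[1L], solvent = sub$solvent[1L],
      ec50_mM = est$value, censoring = est$censoring,
      bound_mM = est$bound,
      method = if (is.null(est$method)) NA_character_ else est$method,
      sd_mM = est$sd, n_reps = est$n_replicates, scale = scale,
      diagnostics = paste(est$diagnostics, collapse = "; "))
  })
  out <- dplyr::bind_rows(rows)
  out[order(out$species, out$solvent), ]
}

#' Run the full tolerance-assay analysis
#'
#' Executes the whole pipeline on an OD table: growth-rate fitting,
#' percent-of-control conversion, EC50 estimation, and the cross-solvent
#' analytics (normalized tolerance scores, EC50-vs-mu0 regressions where
#' at least three species allow it, toxicity rankings, and percent of
#' solubility plus free-phase classification for solvents with known
#' constants). A decision log records every censoring, extrapolation and
#' zero-growth call so the judgment points of the analysis can be
#' audited.
#'
#' @param od Long OD tibble (see [read_od_csv()]).
#' @param solvents Named list of [solvent_spec()]; pairs whose solvent is
#'   missing from it are skipped by the solubility analytics.
#' @param out_dir Optional directory; when given, writes
#'   `growthrates.csv`, `ec50.csv` and `report.json` there.
#' @param reference Reference species for the tolerance scores (default
#'   `"max"`).
#' @param mode,min_points,r2_min,... Stage options, see
#'   [estimate_ec50_table()] and [fit_growth_table()].
#' @return List of class `soltol_report`: `growth`, `mu0`, `ec50`,
#'   `scores`, `regressions` (`NULL` when too few species), `ranking`,
#'   `solubility` (tibble with percent-of-solubility and free-phase
#'   classification), `log` (character vector).
#' @export
run_report <- function(od, solvents = default_solvents(), out_dir = NULL,
                       reference = "max", mode = "replicate",
                       min_points = 5L, r2_min = 0.99, ...) {
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))

  fits <- fit_growth_table(od, min_points = min_points, r2_min = r2_min)
  for (i in which(fits$zero_growth)) {
    note("zero growth assigned: %s / %s at %.4g mM (replicate %s, max OD %.3f)",
         fits$species[i], fits$solvent[i], fits$conc_mM[i],
         fits$replicate[i], fits$max_od[i])
  }
  rel <- relative_growth_table(fits)
  ec50 <- estimate_ec50_table(rel, mode = mode, ...)
  for (i in seq_len(nrow(ec50))) {
    if (ec50$censoring[i] != "point") {
      note("censored EC50 (%s at %.4g mM): %s / %s", ec50$censoring[i],
           ec50$bound_mM[i], ec50$species[i], ec50$solvent[i])
    } else if (identical(ec50$method[i], "extrapolated")) {
      note("EC50 by extrapolation: %s / %s = %.4g mM", ec50$species[i],
           ec50$solvent[i], ec50$ec50_mM[i])
    }
    if (nzchar(ec50$diagnostics[i])) {
      note("%s / %s: %s", ec50$species[i], ec50$solvent[i],
           ec50$diagnostics[i])
    }
  }

  known <- ec50[ec50$solvent %in% names(solvents), ]
  panel <- species_panel(known, rename_mu0(rel$mu0), solvents)
  scores <- normalized_tolerance_scores(panel, reference = reference)
  regressions <- NULL
  if (length(unique(known$species)) >= 3L) {
    regressions <- tryCatch(
      dplyr::bind_rows(
        regress_ec50_vs_mu0(panel, per_solvent = TRUE),
        regress_ec50_vs_mu0(panel, per_solvent = FALSE,
                            reference = reference)),
      error = function(e) {
        note("regression skipped: %s", conditionMessage(e))
        NULL
      })
  } else {
    note("regression skipped: fewer than 3 species")
  }
  ranking <- toxicity_ranking(panel)

  solub <- dplyr::bind_rows(lapply(seq_len(nrow(known)), function(i) {
    row <- known[i, ]
    sv <- solvents[[row$solvent]]
    ps <- percent_of_solubility(row, sv)
    tibble::tibble(species = row$species, solvent = row$solvent,
                   percent_of_solubility = ps$percent,
                   rounded = ps$rounded, comparator = ps$comparator,
                   free_phase_tolerant =
                     classify_free_phase_tolerance(row, sv))
  }))

  report <- structure(
    list(growth = fits, mu0 = rel$mu0, ec50 = ec50, scores = scores,
         regressions = regressions, ranking = ranking,
         solubility = solub, log = log),
    class = "soltol_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(as.data.frame(fits),
                     file.path(out_dir, "growthrates.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(ec50), file.path(out_dir, "ec50.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(mu0 = rel$mu0, scores = scores$scores,
           score_summary = scores$summary, regressions = regressions,
           ranking = ranking$ranking,
           ranking_violations = ranking$violations,
           solubility = solub, log = log),
      file.path(out_dir, "report.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' @export
print.soltol_report <- function(x, ...) {
  cat(sprintf("<soltol_report> %d species, %d species x solvent EC50 rows\n",
              nrow(x$mu0), nrow(x$ec50)))
  print(x$ec50, n = 10)
  cat(sprintf("%d decision-log entries\n", length(x$log)))
  invisible(x)
}

#' @keywords internal
#' @noRd
rename_mu0 <- function(mu0_tbl) {
  tibble::tibble(species = mu0_tbl$species, mu0 = mu0_tbl$mu0)
}
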