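#' Assemble a species panel for cross-solvent analytics
#'
#' Bundles the EC50 table, the no-solvent growth rates and the solvent
#' constants that the tolerance analytics operate on.
#'
#' @param ec50 Data frame with one row per species x solvent: columns
#'   `species`, `solvent`, `ec50_mM` (point estimate, `NA` when only a
#'   bound is known), `censoring` (`"point"`, `"left"`, `"right"` or
#'   `"interval"`), `bound_mM` (censoring bound), optionally `lo_mM` and
#'   `hi_mM` (interval knowledge) and `method`.
#' @param mu0 Data frame with columns `species` and `mu0` (1/h, no-solvent
#'   growth rate), or `NULL` when growth rates are unavailable (regressions
#'   then refuse to run).
#' @param solvents Named list of [solvent_spec()] covering every solvent
#'   in `ec50`.
#' @return An object of class `species_panel`.
#' @export
species_panel <- function(ec50, mu0 = NULL, solvents = default_solvents()) {
  ec50 <- tibble::as_tibble(ec50)
  need <- c("species", "solvent", "ec50_mM", "censoring")
  miss <- setdiff(need, names(ec50))
  if (length(miss)) {
    abort_input("ec50 table missing columns: ", paste(miss, collapse = ", "))
  }
  for (opt in c("bound_mM", "lo_mM", "hi_mM")) {
    if (!opt %in% names(ec50)) ec50[[opt]] <- NA_real_
  }
  bad <- setdiff(ec50$censoring, c("point", "left", "right", "interval"))
  if (length(bad)) {
    abort_input("unknown censoring classes: ", paste(bad, collapse = ", "))
  }
  unknown <- setdiff(unique(ec50$solvent), names(solvents))
  if (length(unknown)) {
    abort_input("no solvent_spec for: ", paste(unknown, collapse = ", "))
  }
  if (!is.null(mu0)) {
    mu0 <- tibble::as_tibble(mu0)
    if (!all(c("species", "mu0") %in% names(mu0))) {
      abort_input("mu0 table needs columns species, mu0")
    }
    if (any(mu0$mu0 <= 0, na.rm = TRUE)) {
      abort_input("mu0 must be positive for included species")
    }
  }
  structure(list(ec50 = ec50, mu0 = mu0, solvents = solvents),
            class = "species_panel")
}

# Single representative concentration for an EC50 record: the point
# estimate, the censoring bound, or the interval midpoint.
#' @keywords internal
#' @noRd
representative_ec50 <- function(row) {
  switch(row$censoring,
    point = row$ec50_mM,
    left = row$bound_mM,
    right = row$bound_mM,
    interval = (row$lo_mM + row$hi_mM) / 2,
    NA_real_)
}

#' @keywords internal
#' @noRd
as_ec50_row <- function(x) {
  if (inherits(x, "ec50_estimate")) {
    return(list(ec50_mM = x$value, censoring = x$censoring,
                bound_mM = x$bound, lo_mM = NA_real_, hi_mM = NA_real_))
  }
  if (is_number(x)) {
    return(list(ec50_mM = as.numeric(x), censoring = "point",
                bound_mM = NA_real_, lo_mM = NA_real_, hi_mM = NA_real_))
  }
  x <- as.list(x)
  if (!all(c("ec50_mM", "censoring") %in% names(x))) {
    abort_input("expected an ec50_estimate, a number, or a record with ",
                "ec50_mM and censoring")
  }
  for (opt in c("bound_mM", "lo_mM", "hi_mM")) {
    if (is.null(x[[opt]])) x[[opt]] <- NA_real_
  }
  x
}

#' EC50 as a percentage of aqueous solubility
#'
#' How close an EC50 sits to the solvent's maximum aqueous solubility --
#' the quantity that separates solvents tolerated only as dilute plumes
#' from those tolerated near saturation or as a free phase.
#'
#' @param ec50 A point EC50 in mmol/L, an [estimate_ec50()] result, or a
#'   curated record (list with `ec50_mM`, `censoring`, bounds).
#' @param solvent A [solvent_spec()].
#' @return List with `percent` (raw), `rounded` (nearest integer) and
#'   `comparator`: `"="` for point estimates, `">"`/`"<"` for right/left
#'   censored records (percent then refers to the bound), `"~"` for
#'   interval records (percent of the midpoint).
#' @examples
#' percent_of_solubility(1, default_solvents()$CT)  # 20%
#' @export
percent_of_solubility <- function(ec50, solvent) {
  stopifnot(inherits(solvent, "solvent_spec"))
  row <- as_ec50_row(ec50)
  rep_val <- representative_ec50(row)
  if (!is.finite(rep_val)) {
    abort_input("EC50 record carries no usable value or bound")
  }
  pct <- 100 * rep_val / solvent$aqueous_solubility
  comparator <- switch(row$censoring, point = "=", right = ">", left = "<",
                       interval = "~")
  list(percent = pct, rounded = round(pct), comparator = comparator)
}

#' Can the species grow with a free solvent phase present?
#'
#' A species is free-phase tolerant for a solvent when its EC50 exceeds
#' the solvent's maximum aqueous solubility: growth still proceeds at or
#' above half the control rate once undissolved solvent is present. Point
#' estimates must strictly exceed the solubility. A right-censored bound
#' at or above the solubility also qualifies, since right-censoring means
#' the true EC50 lies strictly beyond the bound. Left-censored records
#' never qualify; interval records qualify only when the whole interval
#' lies above the solubility.
#'
#' @inheritParams percent_of_solubility
#' @return `TRUE` or `FALSE`.
#' @export
classify_free_phase_tolerance <- function(ec50, solvent) {
  stopifnot(inherits(solvent, "solvent_spec"))
  row <- as_ec50_row(ec50)
  sol <- solvent$aqueous_solubility
  switch(row$censoring,
    point = row$ec50_mM > sol,
    right = row$bound_mM >= sol,
    left = FALSE,
    interval = is.finite(row$lo_mM) && row$lo_mM > sol,
    FALSE)
}

#' Reference-normalized tolerance scores
#'
#' Scores each species' overall solvent tolerance on a common scale: per
#' solvent, the reference species' EC50 is set at 100 percent and every
#' other species' EC50 is expressed as a percentage of it; the per-solvent
#' percentages are then averaged per species. Censored records enter
#' through their representative value (bound or interval midpoint) and
#' are flagged, or can be dropped from the average.
#'
#' @param panel A [species_panel()].
#' @param reference `"max"` (default) to use the per-solvent maximum EC50
#'   as the 100 percent anchor, or a species name; a named reference must
#'   hold a point or right-censored estimate for every solvent.
#' @param censored `"bound"` (default) to score censored records at their
#'   representative value with a flag, or `"drop"` to exclude them from
#'   the per-species average.
#' @return List with `scores` (tibble: species, solvent, score,
#'   censored), `summary` (tibble: species, avg_score, n_solvents,
#'   complete) and `reference`.
#' @export
normalized_tolerance_scores <- function(panel, reference = "max",
                                        censored = c("bound", "drop")) {
  stopifnot(inherits(panel, "species_panel"))
  censored <- match.arg(censored)
  tbl <- panel$ec50
  tbl$rep_value <- vapply(seq_len(nrow(tbl)),
                          function(i) representative_ec50(tbl[i, ]),
                          numeric(1))
  solvs <- unique(tbl$solvent)

  ref_val <- vapply(solvs, function(sv) {
    sub <- tbl[tbl$solvent == sv, ]
    if (identical(reference, "max")) {
      max(sub$rep_value, na.rm = TRUE)
    } else {
      r <- sub[sub$species == reference, ]
      if (nrow(r) != 1L || !r$censoring %in% c("point", "right")) {
        abort_input("reference species '", reference,
                     "' lacks a point or right-censored estimate for ", sv)
      }
      r$rep_value
    }
  }, numeric(1))
  names(ref_val) <- solvs

  scores <- tibble::tibble(
    species = tbl$species,
    solvent = tbl$solvent,
    score = 100 * tbl$rep_value / ref_val[tbl$solvent],
    censored = tbl$censoring != "point")

  use <- if (censored == "drop") scores[!scores$censored, ] else scores
  all_solvs <- length(solvs)
  summary <- use |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(avg_score = mean(.data$score),
                     n_solvents = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(complete = .data$n_solvents == all_solvs)

  list(scores = scores, summary = summary, reference = reference)
}

#' Regress EC50 (or tolerance score) on the solvent-free growth rate
#'
#' Ordinary least-squares fit testing whether faster-growing species
#' tolerate more solvent. With `per_solvent = TRUE`, one regression of
#' EC50 on mu0 per solvent; otherwise a single regression of the averaged
#' normalized tolerance score on mu0.
#'
#' @param panel A [species_panel()] with a `mu0` table.
#' @param per_solvent One regression per solvent (default `TRUE`).
#' @param censored `"bound"` to include censored records at their
#'   representative value, `"drop"` to exclude them.
#' @param ... Passed to [normalized_tolerance_scores()] when
#'   `per_solvent = FALSE`.
#' @return Tibble with columns `response`, `slope`, `intercept`, `r2`,
#'   `n`.
#' @export
regress_ec50_vs_mu0 <- function(panel, per_solvent = TRUE,
                                censored = c("bound", "drop"), ...) {
  stopifnot(inherits(panel, "species_panel"))
  censored <- match.arg(censored)
  if (is.null(panel$mu0)) {
    abort_input("panel has no mu0 table; regressions need growth rates")
  }

  ols_row <- function(label, x, y) {
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3L) {
      abort_input(label, ": need >= 3 species with usable estimates and mu0")
    }
    if (stats::var(x) == 0) {
      abort_input(label, ": mu0 values are constant; regression undefined")
    }
    f <- fast_linfit(x, y)
    tibble::tibble(response = label, slope = f$slope,
                   intercept = f$intercept, r2 = f$r2, n = length(x))
  }

  if (per_solvent) {
    tbl <- panel$ec50
    tbl$rep_value <- vapply(seq_len(nrow(tbl)),
                            function(i) representative_ec50(tbl[i, ]),
                            numeric(1))
    if (censored == "drop") tbl <- tbl[tbl$censoring == "point", ]
    tbl <- dplyr::left_join(tbl, panel$mu0, by = "species")
    dplyr::bind_rows(lapply(unique(tbl$solvent), function(sv) {
      sub <- tbl[tbl$solvent == sv, ]
      ols_row(sv, sub$mu0, sub$rep_value)
    }))
  } else {
    sc <- normalized_tolerance_scores(panel, censored = censored, ...)
    d <- dplyr::inner_join(sc$summary, panel$mu0, by = "species")
    ols_row("avg_normalized_score", d$mu0, d$avg_score)
  }
}

#' Rank solvents by toxicity per species
#'
#' Orders each species' solvents from most to least toxic (ascending
#' EC50, using representative values for censored records) and checks the
#' ordering against the hydrophobicity rule: higher log Pow solvents are
#' expected to be more toxic. Every adjacent-free pair whose EC50 order
#' contradicts the log Pow order is reported as a violation.
#'
#' @param panel A [species_panel()].
#' @return List with `ranking` (tibble: species, rank, solvent, ec50_rep,
#'   log_pow, censoring) and `violations` (tibble: species, more_toxic,
#'   less_toxic, log_pow_more, log_pow_less), where each row records a
#'   pair in which the lower-log-Pow solvent was the more toxic.
#' @export
toxicity_ranking <- function(panel) {
  stopifnot(inherits(panel, "species_panel"))
  tbl <- panel$ec50
  tbl$rep_value <- vapply(seq_len(nrow(tbl)),
                          function(i) representative_ec50(tbl[i, ]),
                          numeric(1))
  tbl$log_pow <- vapply(tbl$solvent,
                        function(sv) panel$solvents[[sv]]$log_pow,
                        numeric(1))

  rank_rows <- list()
  viol_rows <- list()
  for (sp in unique(tbl$species)) {
    sub <- tbl[tbl$species == sp & is.finite(tbl$rep_value), ]
    sub <- sub[order(sub$rep_value), ]
    rank_rows[[sp]] <- tibble::tibble(
      species = sp, rank = seq_len(nrow(sub)), solvent = sub$solvent,
      ec50_rep = sub$rep_value, log_pow = sub$log_pow,
      censoring = sub$censoring)
    if (nrow(sub) >= 2L) {
      for (i in seq_len(nrow(sub) - 1L)) {
        for (j in seq.int(i + 1L, nrow(sub))) {
          if (sub$rep_value[i] < sub$rep_value[j] &&
              sub$log_pow[i] < sub$log_pow[j]) {
            viol_rows[[length(viol_rows) + 1L]] <- tibble::tibble(
              species = sp,
              more_toxic = sub$solvent[i], less_toxic = sub$solvent[j],
              log_pow_more = sub$log_pow[i], log_pow_less = sub$log_pow[j])
          }
        }
      }
    }
  }
  list(ranking = dplyr::bind_rows(rank_rows),
       violations = if (length(viol_rows)) dplyr::bind_rows(viol_rows)
                    else tibble::tibble(species = character(0),
                                        more_toxic = character(0),
                                        less_toxic = character(0),
                                        log_pow_more = numeric(0),
                                        log_pow_less = numeric(0)))
}

#' Curated published EC50 panel
#'
#' Loads the curated reference panel shipped with the package: EC50
#' values, censoring bounds and qualitative tolerance flags for eight
#' anaerobic bacteria exposed to PCE, CT, CF and 1,2-DCA, transcribed
#' from the published text of the study this assay design follows. Cells
#' for which only a range or bound was printed are recorded as interval
#' or censored records -- no value was read off a figure. Each record
#' carries a `source_note` summarizing the printed statement behind it.
#'
#' @return Tibble with columns `species`, `solvent`, `censoring`,
#'   `ec50_mM`, `bound_mM`, `lo_mM`, `hi_mM`, `method`,
#'   `above_pce_solubility`, `no_growth_at_lowest`, `source_note`.
#' @export
load_curated_results <- function() {
  path <- system.file("extdata", "curated_ec50.csv", package = "soltol",
                      mustWork = TRUE)
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  tbl$above_pce_solubility <- as.logical(tbl$above_pce_solubility)
  tbl$no_growth_at_lowest <- as.logical(tbl$no_growth_at_lowest)
  tibble::as_tibble(tbl)
}
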