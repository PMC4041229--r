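---
title: "Methods: quantifying solvent tolerance in sealed anaerobic cultures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying solvent tolerance in sealed anaerobic cultures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soltol)
```

soltol analyses growth-inhibition assays in which anaerobic bacteria are
cultured in sealed vials together with volatile chlorinated solvents
(chlorinated aliphatic hydrocarbons: perchloroethene PCE, carbon
tetrachloride CT, chloroform CF and 1,2-dichloroethane DCA). The endpoint
is the EC50: the dissolved solvent concentration that halves the specific
growth rate relative to solvent-free controls. This vignette describes the
models and numerical choices behind each stage, and what the packaged
simulator can and cannot tell you about real data.

## Dose partitioning in a sealed vial

A volatile solvent dosed into a sealed vial distributes between the
medium and the headspace. At equilibrium the dimensionless Henry constant
$H_{cc}$ fixes the ratio of gas to aqueous concentration, so a closed
mass balance over a total amount $n$ (µmol), liquid volume $V_{aq}$ and
headspace $V_{gas}$ (mL) gives the dissolved concentration in mmol L⁻¹:

$$C_{aq} = \frac{n}{V_{aq} + H_{cc}\,V_{gas}}.$$

If $C_{aq}$ would exceed the solvent's aqueous solubility, the aqueous
phase saturates, the headspace equilibrates with the saturated solution,
and the remainder is a free non-aqueous phase (`partition_dose()` reports
it as such). The *nominal* concentration $n / V_{aq}$ is always reported
too: above the solubility limit it is the conventional axis for dosing,
since the dissolved concentration is pinned at saturation.

Temperature enters through the Henry table of each `solvent_spec()`.
Between tabulated temperatures, $\ln H_{cc}$ is interpolated linearly in
$1/T$ (van't Hoff form), which is exact when the enthalpy of
volatilization is constant over the narrow assay range. Outside the
table, the nearest endpoint is used with a warning rather than an error,
because incubation temperatures legitimately vary by species (24--37 °C
here). The shipped constants in `inst/extdata/solvents.yaml` are
literature values (the PCE and CT solubilities of 0.9 and 5 mmol L⁻¹ are
the widely used limits; Henry constants and the CF/DCA solubilities are
implementer-sourced compilations) and are meant to be replaced by
site-specific numbers via `read_solvents_yaml()` when available.
Co-solvent effects of the ethanol carrier are ignored: ethanol-only
controls are experimentally indistinguishable from solvent-free controls
at the volumes used (≤ 100 µL).

Units are fixed internally: concentrations mmol L⁻¹, amounts µmol,
volumes mL, temperatures °C.

## Growth rates from OD600 series

The specific growth rate is the slope of $\ln \mathrm{OD}_{600}$ against
time during exponential growth,
$\mu = \ln(X_t / X_0)\,/\,t$ with time zero at the onset of exponential
growth; the least-squares slope used here coincides with that two-point
form on exact exponentials for any point pair in the window.

Window detection (`detect_exponential_window()`) scans all contiguous
windows of at least `min_points` readings, keeps those whose log-linear
fit reaches `r2_min` with positive slope, and returns the steepest.
Two defaults matter:

* `min_points = 5`, `r2_min = 0.99`. Shorter windows make the
  maximum-slope selector an extreme-value statistic of read noise, which
  is largest on the log scale at low OD; at the simulator's read noise
  (OD SD 0.005) 3-point windows inflate $\mu$ by roughly 10 % while
  5-point windows at $R^2 \ge 0.99$ keep the median relative error near
  3 %. Series shorter than 5 readings fall back to their own length
  (minimum 3).
* In the table-level pipeline (`fit_growth_table()`) the window is
  detected per species on the *no-solvent controls* and shared with that
  species' treated cultures. The assay design justifies this: cultures of
  a species start and cease growing together and differ only in rate, so
  the high-signal controls locate the window far more reliably than a
  strongly inhibited culture whose whole excursion may be a few
  milli-OD. Per-series detection remains available
  (`share_window = FALSE`).

Zero growth ($\mu = 0$) is assigned when a culture never exceeds OD
0.04, when readings decline overall (final below initial and maximum
rise under 0.02 -- the tolerance makes the rule robust to single-read
noise), or when no window qualifies. Non-positive blank-corrected
readings are excluded from log fits.

Treated growth is expressed as a percentage of the control mean $\mu_0$
(set at 100 %); an assay whose controls all fail to grow is invalid and
raises an error.

## EC50 estimation

`estimate_ec50()` follows the interpolation convention of tube-assay
toxicology rather than parametric curve fitting. With the implicit
control point (0, 100 %):

1. no growth already at the lowest tested concentration →
   **left-censored** at that concentration;
2. first downward crossing of 50 % between adjacent points → linear
   **interpolation** inside that segment (non-monotone curves use the
   first crossing, the conservative choice);
3. growth above 50 % everywhere → OLS line of percent on concentration
   (control included), solved for 50 % → **extrapolated**, but only when
   a decline is evident: the fitted slope is negative *and* growth at
   the top tested concentration has fallen below 80 %. Otherwise, or
   when the line reaches 50 at or below the top tested concentration
   (contradicting the observed growth there), the estimate is
   **right-censored** at the top concentration.

The 80 % gate reflects how such assays are read in practice: a series
still at 91 % of control at the top dose shows no decreasing trend worth
extrapolating, whereas extrapolation from 54 % or 70 % only projects a
short distance beyond the tested range. The control point's inclusion in
the extrapolation line uses all information; exclude it with
`include_control = FALSE` if your convention differs.

Replicates are handled replicate-first by default
(`ec50_replicate_stats()`): one EC50 per replicate curve, then mean ±
sample SD over the point estimates, with censoring-class disagreements
resolved by majority and reported in the diagnostics. An average-curve
mode (pool percents per concentration, then estimate once) is available
because either convention is found in the literature; SD is then not
defined.

## Cross-solvent analytics

* `percent_of_solubility()` expresses an EC50 as a percentage of the
  solvent's aqueous solubility -- the quantity that distinguishes
  solvents tolerated near saturation from those tolerated only as dilute
  plumes. Censored records report their bound with a `>`/`<` comparator.
* `classify_free_phase_tolerance()` is true when the EC50 exceeds the
  solubility, i.e. the species still grows at half rate with undissolved
  solvent present. Point estimates must strictly exceed the limit; a
  right-censored bound at the limit also qualifies, because
  right-censoring means the true EC50 lies strictly beyond the bound.
* `normalized_tolerance_scores()` puts species on a common scale: per
  solvent the reference species (by default the per-solvent maximum,
  which in the curated panel is the *Klebsiella* isolate) is set to
  100 % and others are expressed relative to it; the four per-solvent
  percentages are averaged. Censored records enter via their bound
  (flagged) or can be dropped -- both behaviours are offered because the
  published figure does not state which was used.
* `regress_ec50_vs_mu0()` fits unweighted OLS of EC50 (or of the
  averaged score) on the solvent-free growth rate; at least three
  species with usable values are required.
* `toxicity_ranking()` orders solvents per species by EC50 and reports
  violations of the hydrophobicity (log P~o/w~) ordering, such as CT
  being more toxic than PCE despite its marginally lower log P~o/w~.

`load_curated_results()` ships a transcription of the published EC50
panel for eight anaerobic species. Only numbers printed in the text are
recorded; cells published as ranges are `interval` records and
bound-only statements are `left`/`right` censored records, so no value
was read off a figure. Analytics use a representative value per record
(point value, bound, or interval midpoint).

## The simulator and what passing tests mean

`simulate_assay()` generates the full factorial design: 8 species × 4
solvents × 5 concentrations × 3 replicates plus one shared no-solvent
control triplicate per species (one control set per species, matching
how such assays are run; 504 series in total). Each species has a true
$\mu_0$ (defaults span 0.06--0.7 h⁻¹, i.e. stationary phase between
roughly 5 and 70 h), a 2 h lag, inoculation OD 0.02 (a 5 % transfer of a
late-exponential parent) and stationary OD 0.5. Growth under solvent
follows a chosen dose-response shape -- linear
$f(c) = \max(0, 1 - c/2\mathrm{EC50})$ or logistic (Hill) -- both exactly
50 % at the true EC50. Treated cultures grow at $\mu_0 f(c)$ and stop
when the control reaches stationary phase, ending at a lower OD:
cultures start and cease growth together and differ only in rate.
Read noise is additive Gaussian (default SD 0.005 OD, truncated at 0),
reflecting spectrophotometer noise that dominates at the low ODs where
the fit window sits; the stationary plateau is hard, since monitoring
stops at stationary phase. Dose series are geometric around the true
EC50 (span ×4 each way), mimicking a well-designed bracketing series;
`conc_shift` displaces them to study censoring.

Default problem sizes were chosen to exercise the full design while
keeping simulation studies quick: 12 readings per curve, 100 panels for
recovery summaries, 12 panels per side for censoring fidelity. Under
these conditions the pipeline recovers $\mu_0$ with ~2--3 % and EC50
with ~5--6 % median relative error, and flags out-of-range truths as
bounds in ≈100 % of cases; with zero noise and the linear shape the
recovery is exact to floating precision, which pins down the
interpolation algebra.

The simulator deliberately omits several features of real data: lag or
phase-length shifts under solvent stress (real sub-lethal stress can
lengthen lags), multiplicative or autocorrelated OD noise, condensation
and sorption losses, death phases, day-to-day batch effects, and any
mechanistic toxicodynamics. Passing recovery tests therefore shows the
*estimators* are correct and well-behaved at realistic noise, not that
real assays meet the model's assumptions -- the decision log produced by
`run_report()` exists precisely so the judgment calls (window choice,
zero-growth assignments, censoring, extrapolation) can be audited on
real data.

## Degenerate inputs and numerical conventions

* Partitioning: headspace volume 0 gives $C_{aq}$ = nominal; the mass
  balance is exact to relative 1e-9 by construction and property-tested.
* Growth fitting: series need ≥ 3 readings; ties in window slope (exact
  exponentials) resolve to the earliest, then longest window, so a pure
  exponential returns its full span.
* EC50: percents are floored at 0; stimulation above 100 % is allowed;
  an exact 50 % reading at a tested concentration returns that
  concentration.
* Seeds are mandatory in `sim_config()`; simulation restores the
  caller's RNG state, so seeded pipelines are bit-reproducible.
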