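# soltol

Analysis toolkit for **solvent tolerance assays of anaerobic bacteria**
grown in sealed vials with volatile chlorinated solvents (PCE, carbon
tetrachloride, chloroform, 1,2-dichloroethane). It is written for
microbiologists and bioremediation researchers who measure how much
chlorinated solvent a strain can stand before its growth rate halves —
the EC50 — and who need the surrounding plumbing done right: headspace
partitioning, growth-rate extraction, censoring, and cross-solvent
comparisons.

The pipeline covers four stages:

1. **Dose → dissolved concentration.** A dose of volatile solvent in a
   sealed vial partitions between medium and headspace. With total
   amount *n* (µmol), liquid volume *V*aq, headspace *V*gas (mL) and the
   dimensionless Henry constant *H*cc at the incubation temperature,

   *C*aq = *n* / (*V*aq + *H*cc·*V*gas)   [mmol L⁻¹],

   capped at the aqueous solubility, beyond which the excess forms a
   free phase and concentrations are reported as nominal (*n*/*V*aq).
   Henry constants are interpolated in ln *H* vs 1/*T* (van't Hoff)
   between tabulated temperatures.
2. **OD600 → specific growth rate.** μ (h⁻¹) is the least-squares slope
   of ln OD vs time in the exponential window — equal to the classical
   ln(*X*t/*X*0)/*t* on exact exponentials. Cultures that never pass OD
   0.04 or that decline are assigned μ = 0.
3. **Percent-of-control → EC50.** Treated rates are expressed as % of
   the control mean μ₀; the EC50 is the first downward crossing of 50 %
   by linear interpolation, by guarded linear extrapolation when growth
   stays above 50 % everywhere, and left/right-censored bounds at the
   boundaries.
4. **Tolerance analytics.** Percent-of-solubility, free-phase tolerance
   classification (EC50 above solubility), reference-normalized
   tolerance scores averaged across solvents, OLS regressions of EC50 on
   μ₀, and per-species toxicity rankings checked against the log P_o/w
   (hydrophobicity) order.

A fully seeded simulator (`simulate_assay()`) generates the complete
factorial assay with known ground truth, so every stage is testable
without lab data, and `load_curated_results()` ships a curated panel of
published EC50 values for eight anaerobic species for comparison.

## Worked example

```r
library(soltol)
sv <- default_solvents()

# 1 µL of neat carbon tetrachloride in a 25 mL tube with 10 mL medium
partition_dose(sv$CT, vial_setup(10, 15, 30), solvent_dose(1, "neat"))
#> <partition_result> total 10.36 umol: aqueous 0.3249 mM,
#>   headspace 0.4743 mM, nominal 1.036 mM
```

1 µL of CT is 10.36 µmol; at 30 °C two thirds of it sits in the
headspace, so the culture actually experiences 0.32 mmol L⁻¹ — a third
of the nominal concentration. Now a full synthetic assay:

```r
sim <- simulate_assay(default_true_params(),
                      sim_config(noise_sd = 0.005, seed = 42))
report <- run_report(sim$od)
report$ec50[1:4, 1:8]
#> # A tibble: 4 x 8
#>   species solvent ec50_mM censoring bound_mM method        sd_mM n_reps
#> 1 sp01    CF        0.839 point           NA interpolated 0.180       3
#> 2 sp01    CT        0.195 point           NA interpolated 0.0135      3
#> 3 sp01    DCA       1.90  point           NA interpolated 0.266       3
#> 4 sp01    PCE       0.386 point           NA interpolated 0.0442      3
```

Each row is one species × solvent pair: the EC50 in mmol L⁻¹ (mean over
the three replicate curves, with SD), whether it is a point estimate or
a censored bound, and how it was obtained. The report also carries the
normalized tolerance scores (`report$scores$summary` — the most
tolerant species anchors 100 %), percent-of-solubility with free-phase
classification (`report$solubility`), EC50-vs-μ₀ regressions, toxicity
rankings, and a decision log (192 entries here) recording every
zero-growth call, censoring and extrapolation. Against the simulator's
ground truth this run recovers EC50s with a median relative error of
5.8 %.

A thin command-line wrapper over the same functions is shipped at
`inst/scripts/soltol-cli.R` (verbs: `partition`, `simulate`, `growth`,
`ec50`, `report`).

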