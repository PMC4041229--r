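# Physicochemical constants for the four chlorinated aliphatic
# hydrocarbons used in the tolerance assays.
#
# Units: molar_mass_g_mol (g/mol), density_g_ml (g/mL, neat liquid at
# ~20 C), log_pow (dimensionless), solubility_mM (mmol/L, maximum aqueous
# solubility), henry = [[temp_C, Hcc], ...] with Hcc the dimensionless
# gas/aqueous concentration ratio at equilibrium.
#
# Provenance: molar masses and densities are standard handbook values.
# log Pow values are the conventional literature values for these four
# solvents (1,2-DCA 1.48, CF 1.97, CT 2.64, PCE 2.88). PCE solubility
# 0.9 mM (~150 mg/L) and CT solubility 5 mM (~0.77 g/L) are the widely
# cited ambient-temperature limits; CF (~8.0 g/L -> 67 mM) and 1,2-DCA
# (~8.7 g/L -> 87.9 mM) solubilities and all Henry constants are
# implementer-sourced from compilations of experimental air-water
# partitioning data (dimensionless Hcc near 25 C: PCE ~0.72, CT ~1.2,
# CF ~0.15, 1,2-DCA ~0.048), extended over 20-37 C with van't Hoff
# temperature scaling. Replace with site- or batch-specific constants by
# editing a copy of this file and loading it with read_solvents_yaml().

PCE:
  molar_mass_g_mol: 165.83
  density_g_ml: 1.622
  log_pow: 2.88
  solubility_mM: 0.9
  henry:
    - [20, 0.58]
    - [25, 0.72]
    - [30, 0.90]
    - [37, 1.20]

CT:
  molar_mass_g_mol: 153.82
  density_g_ml: 1.594
  log_pow: 2.64
  solubility_mM: 5.0
  henry:
    - [20, 1.00]
    - [25, 1.21]
    - [30, 1.46]
    - [37, 1.88]

CF:
  molar_mass_g_mol: 119.38
  density_g_ml: 1.489
  log_pow: 1.97
  solubility_mM: 67.0
  henry:
    - [20, 0.12]
    - [25, 0.15]
    - [30, 0.19]
    - [37, 0.26]

DCA:
  molar_mass_g_mol: 98.96
  density_g_ml: 1.253
  log_pow: 1.48
  solubility_mM: 87.9
  henry:
    - [20, 0.040]
    - [25, 0.048]
    - [30, 0.058]
    - [37, 0.075]
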