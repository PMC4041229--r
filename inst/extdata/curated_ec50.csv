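species,solvent,censoring,ec50_mM,bound_mM,lo_mM,hi_mM,method,above_pce_solubility,no_growth_at_lowest,source_note
E. coli,PCE,right,NA,0.9,NA,NA,NA,TRUE,FALSE,"grew at or above 50% of mu0 with free-phase PCE present; EC50 above the 0.9 mM solubility limit (nominal scale)"
P. aeruginosa,PCE,right,NA,0.9,NA,NA,NA,TRUE,FALSE,"grew at or above 50% of mu0 with free-phase PCE present; EC50 above the 0.9 mM solubility limit (nominal scale)"
Klebsiella sp.,PCE,point,4.95,NA,NA,NA,extrapolated,TRUE,FALSE,"most PCE-tolerant species; still grew at 54% of mu0 at the highest nominal level tested (4.58 mM); EC50 extrapolated from the linear trend"
Clostridium sp.,PCE,right,NA,0.9,NA,NA,NA,TRUE,FALSE,"grew at or above 50% of mu0 with free-phase PCE present; EC50 above the 0.9 mM solubility limit (nominal scale)"
Paenibacillus sp.,PCE,right,NA,0.9,NA,NA,NA,TRUE,FALSE,"grew at or above 50% of mu0 with free-phase PCE present; EC50 above the 0.9 mM solubility limit (nominal scale)"
S. oneidensis,PCE,interval,NA,NA,0.3,0.4,NA,FALSE,FALSE,"affected by PCE below the free-phase threshold; EC50 reported in the 0.3-0.4 mM range for the sensitive respirers"
G. sulfurreducens,PCE,interval,NA,NA,0.3,0.4,NA,FALSE,FALSE,"affected by PCE below the free-phase threshold; EC50 reported in the 0.3-0.4 mM range for the sensitive respirers"
D. vulgaris,PCE,interval,NA,NA,0.3,0.4,NA,FALSE,FALSE,"affected by PCE below the free-phase threshold; EC50 reported in the 0.3-0.4 mM range for the sensitive respirers"
E. coli,CT,interval,NA,NA,0.5,2.4,NA,FALSE,FALSE,"non-censored CT EC50s fell between 0.5 and 2.4 mM (10-50% of CT aqueous solubility)"
P. aeruginosa,CT,interval,NA,NA,0.5,2.4,NA,FALSE,FALSE,"non-censored CT EC50s fell between 0.5 and 2.4 mM (10-50% of CT aqueous solubility)"
Klebsiella sp.,CT,interval,NA,NA,0.5,2.4,NA,FALSE,FALSE,"non-censored CT EC50s fell between 0.5 and 2.4 mM (10-50% of CT aqueous solubility)"
Clostridium sp.,CT,interval,NA,NA,0.5,2.4,NA,FALSE,FALSE,"non-censored CT EC50s fell between 0.5 and 2.4 mM (10-50% of CT aqueous solubility)"
Paenibacillus sp.,CT,point,2.4,NA,NA,NA,interpolated,FALSE,FALSE,"most CT-tolerant species with an EC50 of 2.4 mM; isolated from a solvent-contaminated site"
S. oneidensis,CT,left,NA,0.08,NA,NA,NA,FALSE,TRUE,"no growth even at the lowest CT level tested (80 uM)"
D. vulgaris,CT,left,NA,0.08,NA,NA,NA,FALSE,TRUE,"no growth even at the lowest CT level tested (80 uM)"
G. sulfurreducens,CT,left,NA,0.03,NA,NA,NA,FALSE,TRUE,"no growth even at the lowest CT level tested (30 uM)"
E. coli,CF,right,NA,3.5,NA,NA,NA,FALSE,FALSE,"CF EC50 above 3.5 mM"
P. aeruginosa,CF,right,NA,3.5,NA,NA,NA,FALSE,FALSE,"CF EC50 above 3.5 mM"
Klebsiella sp.,CF,right,NA,3.5,NA,NA,NA,FALSE,FALSE,"CF EC50 above 3.5 mM"
Clostridium sp.,CF,right,NA,3.5,NA,NA,NA,FALSE,FALSE,"CF EC50 above 3.5 mM"
Paenibacillus sp.,CF,right,NA,3.5,NA,NA,NA,FALSE,FALSE,"CF EC50 above 3.5 mM"
S. oneidensis,CF,right,NA,3.5,NA,NA,NA,FALSE,FALSE,"CF EC50 above 3.5 mM"
G. sulfurreducens,CF,point,0.2,NA,NA,NA,interpolated,FALSE,FALSE,"CF EC50 of 0.2 mM"
D. vulgaris,CF,left,NA,0.2,NA,NA,NA,FALSE,TRUE,"most CF-sensitive species; completely inhibited at the lowest CF level tested (0.2 mM)"
E. coli,DCA,right,NA,6.5,NA,NA,NA,FALSE,FALSE,"1,2-DCA EC50 at or above 6.5 mM; least toxic solvent"
P. aeruginosa,DCA,right,NA,6.5,NA,NA,NA,FALSE,FALSE,"1,2-DCA EC50 at or above 6.5 mM; least toxic solvent"
Klebsiella sp.,DCA,right,NA,6.5,NA,NA,NA,FALSE,FALSE,"1,2-DCA EC50 at or above 6.5 mM; least toxic solvent"
Clostridium sp.,DCA,right,NA,6.5,NA,NA,NA,FALSE,FALSE,"1,2-DCA EC50 at or above 6.5 mM; least toxic solvent"
Paenibacillus sp.,DCA,right,NA,6.5,NA,NA,NA,FALSE,FALSE,"1,2-DCA EC50 at or above 6.5 mM; least toxic solvent"
S. oneidensis,DCA,right,NA,6.5,NA,NA,NA,FALSE,FALSE,"1,2-DCA EC50 at or above 6.5 mM; least toxic solvent"
G. sulfurreducens,DCA,point,6.5,NA,NA,NA,extrapolated,FALSE,FALSE,"still grew at 70% of mu0 at the highest 1,2-DCA level tested (3.72 mM); EC50 of 6.5 mM obtained by extrapolation"
D. vulgaris,DCA,right,NA,6.5,NA,NA,NA,assigned,FALSE,"grew at 91% of mu0 at the highest 1,2-DCA level tested (4.65 mM) with no declining trend; assigned the same minimum EC50 as G. sulfurreducens"
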