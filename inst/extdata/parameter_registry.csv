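"code","name","units","kind","role","default","low","high","pdf","active"
"X1","Maximum specific fermentation rate","1/d","kinetic",,3,1.5,4.5,"uniform",FALSE
"X2","Fermentation half-saturation coefficient","mgCOD/L","kinetic",,4,2,6,"uniform",FALSE
"X3","Fermentable substrate half-saturation for heterotrophs","mgCOD/L","kinetic",,4,2,6,"uniform",FALSE
"X4","Alkalinity half-saturation coefficient","mmolHCO3/L","kinetic",,0.1,0.05,0.15,"uniform",FALSE
"X5","Anaerobic hydrolysis reduction factor","-","kinetic",,0.1,0.05,0.15,"uniform",FALSE
"X6","Anoxic hydrolysis reduction factor","-","kinetic",,0.6,0.3,0.9,"uniform",FALSE
"X7","Ammonia half-saturation for heterotrophic synthesis","mgN/L","kinetic",,0.05,0.025,0.075,"uniform",FALSE
"X8","Phosphorus half-saturation for growth","mgP/L","kinetic",,0.01,0.005,0.015,"uniform",FALSE
"X9","Colloidal substrate flocculation rate","1/d","kinetic",,0.15,0.075,0.225,"uniform",FALSE
"X10","Maximum specific growth rate of heterotrophs","1/d","kinetic","mu_H",6,3,9,"uniform",TRUE
"X11","Reduction factor for denitrification on nitrate-N","-","kinetic",,0.48,0.24,0.72,"uniform",FALSE
"X12","Reduction factor for denitrification on nitrite-N","-","kinetic","eta_NO2",0.48,0.24,0.72,"uniform",TRUE
"X13","Half-saturation of readily biodegradable substrate","mgCOD/L","kinetic","K_S",20,10,30,"uniform",TRUE
"X14","Oxygen half-saturation for heterotrophic growth","mgO2/L","kinetic","K_OH",0.2,0.1,0.3,"uniform",TRUE
"X15","Oxygen inhibition coefficient for denitrification","mgO2/L","kinetic","K_O_den",0.2,0.1,0.3,"uniform",TRUE
"X16","Aerobic heterotrophic decay rate","1/d","kinetic","b_H",0.62,0.31,0.93,"uniform",TRUE
"X17","Nitrate half-saturation for anoxic growth","mgN/L","kinetic","K_NO3",0.5,0.25,0.75,"uniform",TRUE
"X18","Nitrite half-saturation for anoxic growth","mgN/L","kinetic","K_NO2",0.5,0.25,0.75,"uniform",TRUE
"X19","Oxygen half-saturation for hydrolysis inhibition","mgO2/L","kinetic",,0.2,0.1,0.3,"uniform",FALSE
"X20","Maximum growth rate for ammonia oxidizer","1/d","kinetic","mu_AOB",0.9,0.45,1.35,"uniform",TRUE
"X21","Ammonia half-saturation for ammonia oxidizer","mgN/L","kinetic","K_NH",0.7,0.35,1.05,"uniform",TRUE
"X22","Oxygen half-saturation for autotrophic growth","mgO2/L","kinetic","K_OA",0.4,0.2,0.6,"uniform",TRUE
"X23","Autotrophic decay rate","1/d","kinetic","b_A",0.17,0.085,0.255,"uniform",TRUE
"X24","Maximum acetate uptake rate for phosphorus accumulators","1/d","kinetic",,3,1.5,4.5,"uniform",FALSE
"X25","Storage-polymer half-saturation for phosphorus accumulators","gCOD/gCOD","kinetic",,0.01,0.005,0.015,"uniform",FALSE
"X26","Phosphorus accumulator lysis rate","1/d","kinetic",,0.2,0.1,0.3,"uniform",FALSE
"X27","Maximum growth rate for nitrite oxidizer","1/d","kinetic","mu_NOB",0.7,0.35,1.05,"uniform",TRUE
"X28","Nitrite half-saturation for nitrite oxidizer","mgN/L","kinetic","K_NO2_NOB",0.5,0.25,0.75,"uniform",TRUE
"X29","Anoxic reduction factor for autotrophic decay","-","kinetic",,0.5,0.25,0.75,"uniform",FALSE
"X30","Maximum specific hydrolysis rate","1/d","kinetic","k_h",3,1.5,4.5,"uniform",TRUE
"X31","Hydrolysis half-saturation coefficient","gCOD/gCOD","kinetic","K_X",0.03,0.015,0.045,"uniform",TRUE
"X32","Ammonification rate coefficient","m3/(gCOD.d)","kinetic","k_a",0.08,0.04,0.12,"uniform",TRUE
"X33","Biomass attachment rate onto media","1/d","kinetic","k_att",0.4,0.2,0.6,"uniform",TRUE
"X34","Biofilm detachment rate","1/d","kinetic","k_det",0.05,0.025,0.075,"uniform",TRUE
"X35","Maximum growth rate of fermenting organisms","1/d","kinetic",,3,1.5,4.5,"uniform",FALSE
"X36","Volatile fatty acid half-saturation","mgCOD/L","kinetic",,4,2,6,"uniform",FALSE
"X37","Maximum growth rate of methylotrophs","1/d","kinetic",,1.3,0.65,1.95,"uniform",FALSE
"X38","Methanol half-saturation","mgCOD/L","kinetic",,0.5,0.25,0.75,"uniform",FALSE
"X39","Nitrous-oxide reduction rate coefficient","1/d","kinetic",,0.5,0.25,0.75,"uniform",FALSE
"X40","Free-ammonia inhibition coefficient for nitrite oxidation","mgN/L","kinetic",,1,0.5,1.5,"uniform",FALSE
"X41","Free-nitrous-acid inhibition coefficient","mgN/L","kinetic",,0.2,0.1,0.3,"uniform",FALSE
"X42","Assimilative nitrate reduction rate","1/d","kinetic",,0.1,0.05,0.15,"uniform",FALSE
"X43","Maximum specific colloid adsorption rate","1/d","kinetic",,0.8,0.4,1.2,"uniform",FALSE
"X44","Adsorbed substrate hydrolysis rate","1/d","kinetic",,2,1,3,"uniform",FALSE
"X45","Endogenous respiration rate under anoxia","1/d","kinetic",,0.3,0.15,0.45,"uniform",FALSE
"X46","Maximum specific denitrification rate on storage products","1/d","kinetic",,0.7,0.35,1.05,"uniform",FALSE
"X47","Storage yield under aerobic conditions","gCOD/gCOD","kinetic",,0.85,0.425,1.275,"uniform",FALSE
"X48","Storage yield under anoxic conditions","gCOD/gCOD","kinetic",,0.8,0.4,1.2,"uniform",FALSE
"X49","Half-saturation of storage products","gCOD/gCOD","kinetic",,1,0.5,1.5,"uniform",FALSE
"X50","Maximum specific storage rate","1/d","kinetic",,5,2.5,7.5,"uniform",FALSE
"X51","Oxygen half-saturation for storage","mgO2/L","kinetic",,0.2,0.1,0.3,"uniform",FALSE
"X52","Aerobic heterotrophic yield on soluble substrate","mgCOD/mgCOD","stoichiometric","Y_H_aer",0.666,0.333,0.999,"uniform",TRUE
"X53","Anoxic heterotrophic yield on soluble substrate","mgCOD/mgCOD","stoichiometric","Y_H_anx",0.533,0.2665,0.7995,"uniform",TRUE
"X54","Ammonia oxidizer yield","gCOD/gN","stoichiometric","Y_AOB",0.18,0.09,0.27,"uniform",TRUE
"X55","Nitrite oxidizer yield","gCOD/gN","stoichiometric","Y_NOB",0.06,0.03,0.09,"uniform",TRUE
"X56","Fermentation yield","gCOD/gCOD","stoichiometric",,0.18,0.09,0.27,"uniform",FALSE
"X57","Yield of phosphorus accumulators","gCOD/gCOD","stoichiometric",,0.639,0.3195,0.9585,"uniform",FALSE
"X58","Polyphosphate storage yield","gP/gCOD","stoichiometric",,0.4,0.2,0.6,"uniform",FALSE
"X59","Yield of methylotrophs","gCOD/gCOD","stoichiometric",,0.45,0.225,0.675,"uniform",FALSE
"X60","Fraction of inert COD in slowly biodegradable substrate","-","stoichiometric",,0.05,0.025,0.075,"uniform",FALSE
"X61","Unbiodegradable fraction from cell decay","-","stoichiometric","f_U",0.08,0.04,0.12,"uniform",TRUE
"X62","Nitrogen content of active biomass","gN/gCOD","stoichiometric","i_XB",0.086,0.043,0.129,"uniform",TRUE
"X63","Nitrogen content of particulate inert products","gN/gCOD","stoichiometric",,0.06,0.03,0.09,"uniform",FALSE
"X64","Nitrogen content of soluble inerts","gN/gCOD","stoichiometric",,0.01,0.005,0.015,"uniform",FALSE
"X65","Phosphorus content of active biomass","gP/gCOD","stoichiometric",,0.02,0.01,0.03,"uniform",FALSE
"X66","Phosphorus content of inert products","gP/gCOD","stoichiometric",,0.01,0.005,0.015,"uniform",FALSE
"X67","COD of colloidal influent fraction","gCOD/gCOD","stoichiometric",,0.15,0.075,0.225,"uniform",FALSE
"X68","Soluble fraction of decay products","-","stoichiometric",,0.05,0.025,0.075,"uniform",FALSE
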