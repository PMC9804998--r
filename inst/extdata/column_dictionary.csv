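column,class,units,mandatory,description
study_id,character,,TRUE,opaque identifier of the source study
species,character,,FALSE,species name as reported
pft,character,,TRUE,plant functional type label
growth_form,character,,FALSE,herbaceous or woody (extreme-value thresholds)
gm_value,numeric,see gm_units,TRUE,mesophyll conductance as reported
gm_units,character,,TRUE,"one of mol_m2_s, mol_m2_s_bar, umol_m2_s_Pa"
method,character,,FALSE,"isotope, fluorescence, curve_fitting or other"
T_meas,numeric,degC,FALSE,leaf temperature during measurement
PPFD,numeric,umol m-2 s-1,FALSE,measurement irradiance
CO2_meas,numeric,umol mol-1,FALSE,measurement CO2 concentration
pressure,numeric,kPa,FALSE,"atmospheric pressure, if reported"
elevation,numeric,m,FALSE,"site elevation, if pressure missing"
already_standardised,logical,,FALSE,gm reported at 25 degC in the source
An,numeric,umol m-2 s-1,FALSE,light-saturated net photosynthesis
gs_c,numeric,mol m-2 s-1,FALSE,stomatal conductance to CO2
Ci,numeric,umol mol-1,FALSE,intercellular CO2 concentration
Ca,numeric,umol mol-1,FALSE,ambient CO2 concentration
Anp,numeric,umol m-2 s-1,FALSE,net photosynthesis at Cc = Ci
Sc,numeric,m2 m-2,FALSE,chloroplast surface area exposed to airspaces per leaf area
Sm,numeric,m2 m-2,FALSE,mesophyll surface area exposed to airspaces per leaf area
Tcw,numeric,um,FALSE,mesophyll cell-wall thickness
LMA,numeric,g m-2,FALSE,leaf dry mass per area
leaf_thickness,numeric,um,FALSE,leaf thickness
density,numeric,g cm-3,FALSE,leaf density
porosity,numeric,fraction,FALSE,mesophyll porosity
N_area,numeric,g m-2,FALSE,leaf nitrogen content per area
K_area,numeric,g m-2,FALSE,leaf potassium content per area
rubisco,numeric,g m-2,FALSE,Rubisco content per area
Vcmax_Cc,numeric,umol m-2 s-1,FALSE,maximum carboxylation rate on a Cc basis
stomatal_density,numeric,mm-2,FALSE,stomatal density
stomatal_length,numeric,um,FALSE,stomatal length
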