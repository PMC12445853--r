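# leaflapse trait catalog, schema version 1
name,symbol,category,mechanisms,timescale_min,timescale_max,description,units,key_refs
gs,g_s,stomata_hydraulics,physiological,minutes,hours,Stomatal conductance; diurnally fluctuating aperture response driven by guard-cell turgor,mol m-2 s-1,review:stomata-hydraulics
ci,c_i,stomata_hydraulics|photosynthetic_biochemistry,physiological,seconds,hours,Leaf-internal CO2; tracks ambient CO2 nearly instantaneously and is co-regulated by gs and CO2 drawdown,Pa,review:stomata-hydraulics
psi_leaf,Psi_leaf,stomata_hydraulics,physiological,minutes,hours,Leaf water potential; follows the diurnal stomatal and transpiration dynamics,MPa,review:stomata-hydraulics
kleaf,K_leaf,stomata_hydraulics,physiological|phenotypic,minutes,months,Leaf hydraulic conductance; diurnal dynamics plus longer declines under gradual dehydration,mmol m-2 s-1 MPa-1,review:stomata-hydraulics
gs_operational,g_s(op),stomata_hydraulics,phenotypic,weeks,months,Operational stomatal conductance; the setpoint around which diurnal gs fluctuates; acclimates with photosynthetic capacity,mol m-2 s-1,review:framework
gsmax,g_smax,stomata_hydraulics,phenotypic|evolutionary,years,decades,Anatomical maximum stomatal conductance set by stomatal density and pore geometry of newly developed leaves,mol m-2 s-1,review:stomata-hydraulics
vla,VLA,stomata_hydraulics|morphology_lifespan,phenotypic|evolutionary,years,centuries,Vein length per unit leaf area (vein density); less plastic than stomatal density within lineages,mm mm-2,review:stomata-hydraulics
hydraulic_capacity,K_leaf_max,stomata_hydraulics,evolutionary,decades,centuries,Maximum leaf hydraulic conductance set by vein architecture and xylem anatomy,mmol m-2 s-1 MPa-1,review:stomata-hydraulics
vcmax,V_cmax,photosynthetic_biochemistry,phenotypic,weeks,weeks,Maximum carboxylation rate of Rubisco; acclimates through enzyme allocation,umol m-2 s-1,review:biochemistry
jmax,J_max,photosynthetic_biochemistry,phenotypic,weeks,weeks,Maximum electron transport rate; acclimates alongside Vcmax with a declining ratio under warming and elevated CO2,umol m-2 s-1,review:biochemistry
photosynthetic_pathway,,photosynthetic_biochemistry,evolutionary,centuries,millions_of_years,Photosynthetic pathway (C3 / C4 / CAM); requires coordinated anatomical and biochemical evolution,,review:biochemistry
asat,A_sat,photosynthetic_biochemistry|stomata_hydraulics,evolutionary,decades,centuries,Light-saturated photosynthetic capacity; coupled to evolutionary increases in leaf hydraulic conductance,umol m-2 s-1,review:stomata-hydraulics
lma,LMA,morphology_lifespan,phenotypic|evolutionary,years,centuries,Leaf dry mass per area; structural investment axis of the leaf economics spectrum (LMA = LVA x LD),g m-2,review:morphology
ld,LD,morphology_lifespan,phenotypic|evolutionary,years,centuries,Leaf density; responds to temperature and CO2 through cell expansion and starch accumulation,g cm-3,review:morphology
lva,LVA,morphology_lifespan,phenotypic|evolutionary,years,centuries,Leaf volume per area (thickness); increases under high light with added mesophyll layers,cm3 m-2,review:morphology
ll,LL,morphology_lifespan,phenotypic|evolutionary,years,centuries,Leaf lifespan; co-varies with LMA to return construction costs,months,review:morphology
genome_size,,morphology_lifespan,evolutionary,millions_of_years,millions_of_years,Genome size; sets minimum cell size and thereby coordinates stomatal vein and mesophyll dimensions,Gbp,review:discussion
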