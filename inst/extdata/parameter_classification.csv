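parameter,competition,organ,process
b1Bl,light,leaf,allocation
b2Bl,light,leaf,allocation
b1Bs,unclassified,stem,allocation
b2Bs,unclassified,stem,allocation
q,water,root,allocation
b1Rd,water,root,allocation
b2Rd,water,root,allocation
b1Ht,light,stem,allocation
b2Ht,light,stem,allocation
reproduction_carbon,unclassified,seed,allocation
root_beta,water,root,water_use
SRA,water,root,water_use
K_max,water,stem,water_use
K_exp,water,stem,water_use
P50,water,stem,water_use
wood_capacitance,water,stem,water_use
leaf_capacitance,water,leaf,water_use
stoma_psi_b,water,leaf,water_use
stoma_psi_c,water,leaf,water_use
leaf_TLP,water,leaf,water_use
V_m0,light,leaf,photosynthesis
quantum_efficiency,light,leaf,photosynthesis
stomatal_slope,light,leaf,photosynthesis
root_respiration,water,root,respiration
dark_respiration,light,leaf,respiration
growth_respiration,unclassified,entire_plant,respiration
mort2,unclassified,entire_plant,mortality
mort3,unclassified,entire_plant,mortality
leaf_turnover,light,leaf,tissue_turnover
root_turnover,water,root,tissue_turnover
SLA,light,leaf,structural
rho,unclassified,stem,structural
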