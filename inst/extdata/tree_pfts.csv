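parameter,early,mid,late
b1Bl,0.013,0.013,0.013
b2Bl,1.9,1.9,1.9
b1Bs,0.19,0.21,0.23
b2Bs,2.44,2.44,2.44
q,1.0,1.0,1.0
b1Rd,1.11,1.11,1.11
b2Rd,0.42,0.42,0.42
b1Ht,0.12,0.115,0.11
b2Ht,0.87,0.87,0.87
reproduction_carbon,0.3,0.3,0.3
root_beta,0.001,0.001,0.001
SRA,38,38,38
K_max,0.012,0.009,0.007
K_exp,2.0,2.0,2.0
P50,180,220,260
wood_capacitance,0.004,0.004,0.004
leaf_capacitance,0.0025,0.0025,0.0025
stoma_psi_b,180,200,230
stoma_psi_c,3,3,3
leaf_TLP,180,210,240
V_m0,24,17,11
quantum_efficiency,0.08,0.07,0.06
stomatal_slope,9,8,8
root_respiration,0.28,0.28,0.28
dark_respiration,0.014,0.013,0.013
growth_respiration,0.33,0.33,0.33
mort2,20,20,20
mort3,0.055,0.025,0.008
leaf_turnover,1.0,0.6,0.45
root_turnover,1.27,1.0,0.9
SLA,16,13.5,11
rho,0.45,0.62,0.78
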