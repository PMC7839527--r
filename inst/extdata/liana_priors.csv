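name,family,a,b,negate,scale,units,prior_median,ed2_default,posterior_median,n_obs,n_studies,cv_ratio
b1Bl,uniform,0.005,0.15,FALSE,1,kg_C/cm^b2Bl,0.0078,0.0086,0.0096,462,4,0.07
b2Bl,uniform,1.6,2.2,FALSE,1,-,1.9,2,1.85,462,4,0.29
b1Bs,uniform,0.15,0.4,FALSE,1,kg_C/cm^b2Bs,0.28,0.28,0.27,436,2,0.69
b2Bs,uniform,2.2,3,FALSE,1,-,2.6,2.69,2.57,436,2,0.96
q,uniform,0.5,1.5,FALSE,1,g_C/g_C,1,1,NA,NA,NA,NA
b1Rd,uniform,0.1,2,TRUE,1,m/m^b2Rd,1.05,1.11,0.25,32,1,0.37
b2Rd,uniform,0.05,0.6,FALSE,1,-,0.325,0.42,0.25,32,1,1.31
b1Ht,uniform,0.05,0.15,FALSE,1,-,0.1,0.11,NA,NA,NA,NA
b2Ht,normal,0.87,0.087,FALSE,1,cm^-1,0.87,0.87,NA,NA,NA,NA
reproduction_carbon,uniform,0.7,0.95,FALSE,1,g_C/g_C,0.83,0.9,NA,NA,NA,NA
root_beta,uniform,0.0001,0.1,FALSE,1,-,0.05,0.001,NA,NA,NA,NA
SRA,uniform,24,72,FALSE,1,m2/kg_C,48,48,NA,NA,NA,NA
K_max,lognormal,-3,0.75,FALSE,1,kg m-1 s-1 m-1,0.05,0.014,0.12,64,13,0.16
K_exp,normal,2,0.5,FALSE,1,-,2,1.93,2.06,47,10,0.24
P50,normal,150,50,TRUE,1,m,150,206.2,122.9,61,12,0.20
wood_capacitance,lognormal,2,0.5,FALSE,0.001,kg kg-1 m-1,0.0074,0.0017,0.0083,6,1,0.49
leaf_capacitance,lognormal,-0.29,0.76,FALSE,0.001,kg kg-1 m-1,0.00075,0.0033,0.0019,7,1,0.16
stoma_psi_b,normal,160,40,TRUE,1,m,160,192.86,NA,NA,NA,NA
stoma_psi_c,uniform,1,5,FALSE,1,-,3,3,NA,NA,NA,NA
leaf_TLP,lognormal,5.42,0.53,TRUE,1,m,225.88,192.86,205.02,7,1,0.22
V_m0,weibull,1.35,40,FALSE,1,umol_C m-2 s-1,21.47,18.75,35.54,39,2,0.08
quantum_efficiency,gamma,4.46,59.7,FALSE,1,-,0.069,0.08,0.057,19,4,0.49
stomatal_slope,lognormal,2.2,0.38,FALSE,1,-,9.025,9,10.48,14,1,0.20
root_respiration,uniform,0.14,0.42,FALSE,1,umol_C kg-1 s-1,0.28,0.28,NA,NA,NA,NA
dark_respiration,gamma,2,132,FALSE,1,-,0.013,0.014,0.028,26,3,0.16
growth_respiration,beta,4.06,7.2,FALSE,1,g_C/g_C,0.35,0.33,NA,NA,NA,NA
mort2,gamma,1.2,0.058,FALSE,1,year^-1,15.36,15,NA,NA,NA,NA
mort3,uniform,0,0.1,FALSE,1,year^-1,0.05,0.063,0.051,18,1,0.50
leaf_turnover,uniform,1.3,2.4,FALSE,1,year^-1,1.85,1.27,NA,NA,NA,NA
root_turnover,weibull,1.6,1.6,FALSE,1,year^-1,1.27,1.27,NA,NA,NA,NA
SLA,weibull,2.1,12.1,FALSE,1,m2/kg_C,20.326,17.88,22.06,70,11,0.10
rho,uniform,0.1,1,FALSE,1,g/cm3,0.55,0.46,0.46,66,12,0.07
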