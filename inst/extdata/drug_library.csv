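name,fu_nonpreg,fu_maternal,fu_fetal,partition_method,K_cell_pls,caco2_papp_cm_s,CL_apical_L_min,P_basolateral_cm_min,P_basolateral_source,K_bc,molecular_weight,dose_mg,route,n_doses,interval_h,infusion_duration_min,tlast_h
acyclovir,0.85,0.88,0.86,PK-Sim Standard,0.74,3.0e-07,0.059,5.2e-05,assumed,1,225.21,400,oral,10,8,NA,12
cefuroxime,0.67,0.73,0.68,Schmitt,0.61,1.2e-06,0.20,2.73e-06,reported,1,424.39,750,iv_bolus,1,NA,NA,8
diazepam,0.020,0.027,0.021,PK-Sim Standard,0.079,8.9e-05,15.1,1.33e-02,assumed,1,284.74,10,iv_bolus,1,NA,NA,24
dolutegravir,0.0070,0.0088,0.0080,Rodgers and Rowland,0.16,2.5e-06,0.43,3.8e-04,assumed,1,419.38,50,oral,10,24,NA,24
emtricitabine,0.96,0.97,0.96,Rodgers and Rowland,0.83,NA,0.019,1.7e-05,assumed,1,247.25,400,oral,1,NA,NA,24
metronidazole,0.89,0.92,0.89,Rodgers and Rowland,0.80,5.7e-05,9.76,8.6e-03,assumed,1,171.15,500,iv_bolus,1,NA,NA,4
ondansetron,0.27,0.33,0.28,Poulin and Theil,0.41,1.8e-05,3.11,1.69e-02,reported,1,293.36,4,iv_bolus,1,NA,NA,6
raltegravir,0.17,0.24,0.23,Rodgers and Rowland,0.28,7.3e-06,1.24,1.1e-03,assumed,1,444.42,400,oral,10,12,NA,12
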