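parameter_id,arm,category,source_state,target_state,mean,sd,distribution
tp_hosp_well_icd,ICD,transition,HOSPITALIZATION,WELL,0.822,,fixed
tp_hosp_death_icd,ICD,transition,HOSPITALIZATION,DEATH,0.178,0.008,beta
tp_hosp_well_pharm,PHARM,transition,HOSPITALIZATION,WELL,0.716,,fixed
tp_hosp_death_pharm,PHARM,transition,HOSPITALIZATION,DEATH,0.284,0.009,beta
tp_compl_well_icd,ICD,transition,COMPLICATION,WELL,0.768,,fixed
tp_compl_rej_icd,ICD,transition,COMPLICATION,REJECTION,0.022,,fixed
tp_compl_death_icd,ICD,transition,COMPLICATION,DEATH,0.21,0.109,beta
tp_rej_well_icd,ICD,transition,REJECTION,WELL,0.822,,fixed
tp_rej_death_icd,ICD,transition,REJECTION,DEATH,0.178,0.008,beta
tp_well_compl_icd,ICD,transition,WELL,COMPLICATION,0.205083,,fixed
tp_well_hosp_icd,ICD,transition,WELL,HOSPITALIZATION,0,,fixed
tp_well_death_icd,ICD,transition,WELL,DEATH,0,,fixed
tp_well_hosp_pharm,PHARM,transition,WELL,HOSPITALIZATION,0.207461,,fixed
tp_well_death_pharm,PHARM,transition,WELL,DEATH,0.002642,,fixed
cost_well_icd,ICD,cost,WELL,,3398,1105,gamma
cost_well_pharm,PHARM,cost,WELL,,741,1246,gamma
cost_compl_icd,ICD,cost,COMPLICATION,,3221,933,gamma
cost_hosp_icd,ICD,cost,HOSPITALIZATION,,2925,1247,gamma
cost_hosp_pharm,PHARM,cost,HOSPITALIZATION,,1465,2024,gamma
cost_death_icd,ICD,cost,DEATH,,2777,,fixed
cost_death_pharm,PHARM,cost,DEATH,,467,,fixed
u_well_icd,ICD,utility,WELL,,0.845,0.124,beta
u_well_pharm,PHARM,utility,WELL,,0.88,0.1,beta
u_compl_icd,ICD,utility,COMPLICATION,,0.75,,fixed
u_hosp_icd,ICD,utility,HOSPITALIZATION,,0.725,,fixed
u_hosp_pharm,PHARM,utility,HOSPITALIZATION,,0.85,,fixed
dr_cost,BOTH,setting,,,0.06,,fixed
dr_outcome,BOTH,setting,,,0.03,,fixed
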