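variable,split1,split2,split3,split4,split5,split6,split7,split8,split9,split10,final
gender,0,1,1,1,0,0,0,0,1,0,0
current_smoking,0,1,0,1,0,0,0,0,0,0,0
year_copd_onset,0,0,1,0,0,0,0,0,1,1,0
age_copd_onset,0,0,0,0,0,0,0,1,0,0,0
age_asthma_onset,0,0,1,0,0,0,0,0,0,0,1
copd_duration,0,1,0,1,0,0,0,0,0,0,0
hypertension,0,0,1,0,0,0,0,1,0,1,0
cerebrovascular_disease,1,0,0,0,1,1,1,0,1,1,1
paod,0,0,0,0,0,0,0,1,0,0,0
cardiovascular_disease,0,0,1,0,0,1,0,1,1,0,0
diabetes,1,1,1,1,0,0,1,1,0,0,1
metabolic_syndrome,1,0,1,0,0,1,0,0,0,1,0
hypercholesterolemia,0,0,0,0,0,0,0,1,1,0,0
hypothyreosis,0,0,1,0,0,0,0,0,0,1,0
alcohol_abuse,1,1,1,1,1,0,1,1,1,1,1
cancer,1,1,1,1,0,0,0,1,1,1,1
atrial_fibrillation,1,1,1,1,1,0,0,0,0,1,1
psychiatric_disease,0,1,1,1,1,1,0,1,1,1,1
bmi,0,0,0,0,1,1,1,0,1,0,1
bmi_change,0,1,1,1,1,0,0,0,0,0,0
dlco_pct,0,0,1,0,0,0,0,0,1,0,0
rv_pct,0,0,0,0,0,1,0,0,0,1,0
fvc_pct,0,0,1,0,0,0,0,0,1,1,0
fev1_pct,0,0,0,0,1,1,1,1,0,0,1
qrs_axis,1,0,0,0,0,0,0,0,1,0,0
qtc_ms,0,1,0,1,0,1,1,0,1,1,1
qrs_ms,0,0,0,0,1,0,0,0,0,0,0
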