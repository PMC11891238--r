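date,period,conc_ng_per_mL,daily_dose_mg,dose_known,weight_kg,scr_mg_per_dL,sex,age,note
2023-01-10,L-AMB,NA,60,TRUE,45,0.86,male,63,"therapy start; SCr back-calculated from reported eGFR 70 (synthetic)"
2023-01-13,L-AMB,40,60,TRUE,45,NA,male,63,"reported level range low end; C/D 30"
2023-01-15,L-AMB,57,NA,FALSE,45,NA,male,63,"reported level range high end; reported C/D <= 36 implies unreported dose change"
2023-01-22,VRCZ,224,NA,FALSE,45,NA,male,63,"peak level on voriconazole; reported C/D 99 implies unreported dose change"
2023-03-15,VRCZ,124,NA,FALSE,45,NA,male,63,"last level on voriconazole; reported C/D 63"
2023-03-20,ISCZ,58,NA,FALSE,45,NA,male,63,"level range low end after switch; reported C/D range 27-41"
2023-03-24,ISCZ,86,NA,FALSE,45,NA,male,63,"level range high end after switch"
2023-03-27,ISCZ,NA,NA,FALSE,45,1.26,male,63,"SCr back-calculated from reported eGFR 46 (synthetic)"
2023-03-29,MCFG,NA,NA,FALSE,45,NA,male,63,"switch to micafungin after persistent vomiting"
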