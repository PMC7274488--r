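participant_id,sex,age_at_recruitment,enrollment_date,self_report_diabetes,age_at_diabetes_diagnosis,insulin_within_first_year,years_since_diabetes_diagnosis
p01,F,55,2007-05-01,FALSE,NA,NA,NA
p02,M,61,2007-05-01,FALSE,NA,NA,NA
p03,F,48,2007-05-01,FALSE,NA,NA,NA
p04,F,52,2007-05-01,FALSE,NA,NA,NA
p05,M,66,2007-05-01,FALSE,NA,NA,NA
p06,F,44,2007-05-01,FALSE,NA,NA,NA
p07,F,59,2007-05-01,FALSE,NA,NA,NA
p08,M,50,2007-05-01,FALSE,NA,NA,NA
p09,F,63,2007-05-01,FALSE,NA,NA,NA
p10,M,57,2007-05-01,FALSE,NA,NA,NA
p11,F,49,2007-05-01,TRUE,30,FALSE,10
p12,M,68,2007-05-01,TRUE,50,TRUE,8
p13,F,62,2007-05-01,TRUE,50,FALSE,5
p14,M,54,2007-05-01,TRUE,50,FALSE,0.5
p15,F,46,2007-05-01,FALSE,NA,NA,NA
p16,M,58,2007-05-01,FALSE,NA,NA,NA
p17,F,51,2007-05-01,FALSE,NA,NA,NA
p18,F,65,2007-05-01,FALSE,NA,NA,NA
p19,M,47,2007-05-01,FALSE,NA,NA,NA
p20,F,60,2007-05-01,TRUE,NA,NA,NA
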