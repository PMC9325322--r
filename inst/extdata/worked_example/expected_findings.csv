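patient_id,molecule,pre_exposed,pim,pim_rule,pim_partner,n_ddi,max_severity,pim_ddi,is_ade,criteria,pathway
P01,dabigatran,TRUE,TRUE,age_ge_75,NA,0,NA,FALSE,FALSE,,continued
P02,apixaban,TRUE,TRUE,age_ge_65_renal,NA,1,moderate,TRUE,TRUE,diagnosis,discontinued_bleeding
P03,warfarin,TRUE,TRUE,warfarin_combo,C01BD01,2,moderate,TRUE,TRUE,inr,discontinued_bleeding
P04,rivaroxaban,TRUE,FALSE,NA,NA,1,minor,FALSE,FALSE,,continued
P05,warfarin,TRUE,FALSE,NA,NA,1,moderate,FALSE,FALSE,,discontinued_surgery
P06,rivaroxaban,TRUE,TRUE,age_ge_75,NA,1,major,TRUE,TRUE,hemoglobin,continued
P07,apixaban,FALSE,FALSE,NA,NA,0,NA,FALSE,NA,NA,initiated_in_hospital
P08,warfarin,TRUE,FALSE,NA,NA,0,NA,FALSE,TRUE,antidote,discontinued_bleeding
P09,dabigatran,TRUE,TRUE,age_ge_65_renal,NA,0,NA,FALSE,FALSE,,discontinued_other
P10,warfarin,TRUE,TRUE,warfarin_combo,J01MA02,1,moderate,TRUE,FALSE,,continued
P11,rivaroxaban,TRUE,FALSE,NA,NA,1,major,FALSE,FALSE,,continued
P12,warfarin,TRUE,TRUE,warfarin_combo,M01AE01,1,moderate,TRUE,TRUE,hemoglobin,discontinued_bleeding
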