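patient_id,admission_date,discharge_date,stay_type,icd10_codes
P01,2016-06-15,2016-06-22,medicine,I48:P
P02,2016-06-15,2016-06-22,medicine,R31:P;N189:A
P03,2016-06-15,2016-06-22,medicine,I48:P
P04,2016-06-15,2016-06-22,medicine,I48:P
P05,2016-06-15,2016-06-20,surgery,I48:P
P06,2016-06-15,2016-06-22,medicine,I48:P
P07,2016-06-15,2016-06-22,medicine,I48:P
P08,2016-06-15,2016-06-22,medicine,I48:P
P09,2016-06-15,2016-06-22,medicine,I48:P;N189:A
P10,2016-06-15,2016-06-22,medicine,I48:P
P11,2016-06-15,2016-06-22,medicine,I48:P
P12,2016-06-15,2016-06-22,medicine,I48:P
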