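patient_id,date,analyte,value
P02,2016-06-16,hemoglobin,12.5
P03,2016-06-16,INR,6.1
P05,2016-06-16,INR,2.5
P06,2016-06-16,hemoglobin,9.8
P08,2016-06-16,INR,2.0
P10,2016-06-16,INR,2.2
P11,2016-06-16,INR,5.0
P12,2016-06-16,INR,2.8
P12,2016-06-16,hemoglobin,11.0
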