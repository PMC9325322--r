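patient_id,atc_code,dispense_date,supply_days
P01,B01AE07,2016-05-25,30
P02,B01AF02,2016-05-25,30
P02,C01BD01,2016-05-25,30
P03,B01AA03,2016-05-25,30
P03,C01BD01,2016-05-25,30
P03,N02BE01,2016-05-25,30
P04,B01AF01,2016-05-25,30
P04,N02AX02,2016-05-25,30
P05,B01AA03,2016-05-25,30
P05,N02BE01,2016-05-25,30
P06,B01AF01,2016-05-25,30
P06,C01BD01,2016-05-25,30
P08,B01AA03,2016-05-25,30
P09,B01AE07,2016-05-25,30
P10,B01AA03,2016-05-25,30
P10,J01MA02,2016-05-25,30
P10,J01FA10,2016-05-25,30
P11,B01AF01,2016-05-25,30
P11,B01AC06,2016-05-25,30
P12,B01AA03,2016-05-25,30
P12,M01AE01,2016-05-25,30
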