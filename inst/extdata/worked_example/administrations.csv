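patient_id,atc_code,admin_date
P01,B01AE07,2016-06-16
P01,B01AE07,2016-06-17
P04,B01AF01,2016-06-16
P04,B01AF01,2016-06-17
P06,B01AF01,2016-06-16
P06,B01AF01,2016-06-17
P07,B01AF02,2016-06-16
P07,B01AF02,2016-06-17
P08,B02BA02,2016-06-16
P10,B01AA03,2016-06-16
P10,B01AA03,2016-06-17
P11,B01AF01,2016-06-16
P11,B01AF01,2016-06-17
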