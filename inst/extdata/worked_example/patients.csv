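patient_id,sex,birth_year_month,index_admission_date
P01,M,1936-05,2016-06-15
P02,F,1946-05,2016-06-15
P03,M,1948-05,2016-06-15
P04,M,1946-05,2016-06-15
P05,F,1939-05,2016-06-15
P06,F,1934-05,2016-06-15
P07,M,1941-05,2016-06-15
P08,M,1926-05,2016-06-15
P09,F,1950-05,2016-06-15
P10,M,1944-05,2016-06-15
P11,M,1951-05,2016-06-15
P12,M,1937-05,2016-06-15
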