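patient_id,sbp,dbp,flow_lmin,baseline_date,followup_date,thrombus_present,growth_mm_per_year
P1,159,87,25.00,2015-12-16,2016-08-18,TRUE,-5.50
P2,119,59,8.89,2015-03-19,2016-11-30,TRUE,0.50
P3,127,61,24.18,2008-04-01,2011-06-15,FALSE,2.43
P4,147,94,26.64,2013-04-06,2016-10-04,FALSE,2.28
P5,191,94,25.00,2016-03-25,2018-10-11,TRUE,1.92
P6,136,63,15.06,2010-03-15,2017-08-25,TRUE,1.83
P7,156,77,26.70,2023-04-10,2023-07-06,TRUE,12.50
P8,183,96,25.00,2009-01-15,2012-03-22,FALSE,1.02
P9,168,80,25.00,2011-10-20,2016-03-24,TRUE,-0.20
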