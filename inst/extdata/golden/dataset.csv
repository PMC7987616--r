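patient_id,practice_id,group_id,match_order,exposed_flag,sex,birth_date,townsend_quintile,ethnicity,patient_start,patient_end,index_date,exit_date,follow_up_days,age_at_index,Stroke_flag,Stroke_event_date,Stroke_days_to_event,BMI_value,BMI_date,Smoking_value,Smoking_date
T01,pr1,1,0,1,female,1960-04-15,3,white,2000-01-01,2014-06-30,2007-06-15,2010-01-10,940,47,1,2010-01-10,940,28.4,2006-09-01,1,2001-01-01
T04,pr1,5,0,1,male,1948-11-05,3,white,2000-01-01,2008-10-31,2003-04-04,2008-10-31,2037,54,0,,,,,,
T07,pr1,6,0,1,female,1990-07-01,3,white,2008-07-01,2014-06-30,2011-11-11,2014-06-30,962,21,0,,,22,2011-05-05,,
T08,pr1,7,0,1,male,1930-01-01,3,white,2000-01-01,2009-07-01,2002-03-04,2009-07-01,2676,72,0,,,,,,
T09,pr2,2,0,1,female,1980-03-10,3,white,2003-05-10,2015-12-31,2004-06-01,2015-11-30,4199,24,1,2015-11-30,4199,,,,
T12,pr1,4,0,1,male,1970-06-06,3,white,2013-06-01,2013-09-01,2013-08-01,2013-09-01,31,43,0,,,,,1,2013-06-15
T13,pr1,3,0,1,male,1996-01-01,3,white,2014-01-01,2014-06-30,2014-03-01,2014-06-30,121,18,0,,,,,,
T14,pr1,1,2,0,female,1961-05-20,3,white,2000-01-01,2014-06-30,2007-06-15,2014-06-30,2572,46,0,,,,,,
T15,pr1,1,1,0,female,1958-09-09,3,white,2000-03-01,2014-06-30,2007-06-15,2014-06-30,2572,48,0,,,,,,
T19,pr1,4,2,0,male,1972-04-04,3,white,2000-01-01,2014-06-30,2013-08-01,2014-06-30,333,41,0,,,,,,
T20,pr1,4,1,0,male,1968-10-10,3,white,2005-06-01,2014-06-30,2013-08-01,2014-06-30,333,44,0,,,,,,
T21,pr2,2,1,0,female,1978-07-07,3,white,2004-01-01,2015-12-31,2004-06-01,2015-12-31,4230,25,0,,,,,,
T22,pr2,2,2,0,female,1984-02-10,3,white,2003-05-10,2015-12-31,2004-06-01,2015-12-31,4230,20,0,,,,,,
T24,pr1,7,1,0,male,1929-04-01,3,white,2000-01-01,2014-06-30,2002-03-04,2003-03-03,364,72,1,2003-03-03,364,,,,
T27,pr1,6,1,0,female,1988-12-25,3,white,2006-12-25,2014-06-30,2011-11-11,2014-06-30,962,22,0,,,,,,
T28,pr1,6,2,0,female,1992-03-30,3,white,2010-03-30,2014-06-30,2011-11-11,2014-06-30,962,19,0,,,,,,
T31,pr1,5,2,0,male,1953-01-17,3,white,2000-01-01,2014-06-30,2003-04-04,2014-06-30,4105,50,0,,,,,,
T32,pr1,5,1,0,male,1951-07-02,3,white,2002-08-01,2014-06-30,2003-04-04,2014-06-30,4105,51,0,,,,,,
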