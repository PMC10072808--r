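participant_id,contact_age_exact,contact_age_min,contact_age_max,settings,physical,duration_cat,frequency_cat,distance_cat
P01,12,,,home_household,TRUE,15to59min,daily,lt1km
P01,11,,,school,FALSE,1to4h,daily,1to9km
P02,,30,39,home_nonhousehold,TRUE,5to14min,occasional,lt1km
P02,65,,,other,FALSE,lt5min,first_time,gt9km
P03,5,,,home_household;school,TRUE,gt4h,daily,lt1km
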