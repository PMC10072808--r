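participant_id,age,sex,residence,district_id,occupation,household_size,n_rooms,diary_day_type,employment_status,diary_complete
P01,10,male,urban,U1,student,4,2,weekday,non-working-age,TRUE
P02,34,female,rural,R2,agriculture_fishing,5,1,weekend,employed,FALSE
P03,70,female,rural,R1,retired,2,1,weekday,non-working-age,TRUE
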