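participant_id,band,physical,count
P02,16-64,TRUE,3
P02,5-15,FALSE,2
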