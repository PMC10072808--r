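# Example dialect: maps a survey export with different column names and
# printed level labels onto the canonical layout.
columns:
  contacts:
    participant_id: respondent_id
    duration_cat: duration
levels:
  duration_cat:
    "< 5 min": lt5min
    "5-14 min": 5to14min
    "15-59 min": 15to59min
    "1-4 h": 1to4h
    "> 4 h": gt4h
  sex:
    M: male
    F: female
settings_sep: ";"
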