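{
  "voc_episode_codes": ["282.42", "282.62", "282.64", "282.69"],
  "scd_codes": ["282.41", "282.42", "282.60", "282.61", "282.62",
                "282.63", "282.64", "282.65", "282.66", "282.67",
                "282.68", "282.69"],
  "trial_exclusion_codes": ["V70.7"],
  "complication_categories": {
    "infectious and parasitic diseases":
      {"codes": ["038", "041", "079", "590", "599"],
       "match_mode": "prefix"},
    "fever": {"codes": ["780.6"], "match_mode": "prefix"},
    "pulmonary disorders":
      {"codes": ["486", "517.3", "518.4", "416.8"],
       "match_mode": "prefix"},
    "cerebrovascular conditions":
      {"codes": ["430", "431", "432", "433", "434", "435", "436",
                 "437", "438"],
       "match_mode": "prefix"},
    "thrombosis/DVT": {"codes": ["453"], "match_mode": "prefix"},
    "aseptic (avascular) bone necrosis":
      {"codes": ["733.4"], "match_mode": "prefix"}
  },
  "study_start": "2009-01-01",
  "study_end": "2013-12-31",
  "identification_start": "2009-07-01",
  "identification_end": "2012-12-31",
  "baseline_days": 183,
  "followup_min_days": 365,
  "episode_gap_days": 3,
  "setting_hierarchy": ["inpatient", "ER", "outpatient", "office",
                        "other"],
  "min_age": 18,
  "rng_seed": 1
}
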