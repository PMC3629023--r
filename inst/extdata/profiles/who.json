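{
  "profile_name": "WHO",
  "included_criteria": [
    "acute_cyanosis", "gasping", "resp_rate_extreme", "shock", "oliguria",
    "clot_failure", "unconsciousness", "cardiac_arrest", "stroke",
    "uncontrollable_fit", "jaundice_preeclampsia",
    "spo2_low", "pao2_fio2_low", "creatinine_high", "bilirubin_high",
    "ph_low", "lactate_high", "thrombocytopenia", "unconscious_ketoacids",
    "vasoactive_drugs", "hysterectomy", "transfusion", "intubation",
    "dialysis", "cpr"
  ],
  "parameter_overrides": {}
}
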