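{
  "profile_name": "Haydom",
  "included_criteria": [
    "acute_cyanosis", "gasping", "resp_rate_extreme", "shock", "oliguria",
    "clot_failure", "unconsciousness", "cardiac_arrest", "stroke",
    "uncontrollable_fit", "jaundice_preeclampsia",
    "spo2_low", "thrombocytopenia",
    "icu_admission", "hysterectomy", "transfusion", "intubation", "cpr",
    "eclampsia", "sepsis", "uterine_rupture"
  ],
  "parameter_overrides": {
    "transfusion": { "transfusion_threshold_units": 1 }
  }
}
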