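{
  "bands": [
    {"hba1c_max": null, "egfr_min": null, "egfr_max": 30, "class": "insulin"},
    {"hba1c_max": 8.0, "egfr_min": 30, "egfr_max": null, "class": "metformin"},
    {"hba1c_max": 9.5, "egfr_min": 30, "egfr_max": null, "class": "combined"},
    {"hba1c_max": null, "egfr_min": 30, "egfr_max": null, "class": "insulin"}
  ]
}
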