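{
  "default_threshold": 7.0,
  "allowed": [6.5, 7.0, 7.5],
  "rules": [
    {"max_age": 45, "complications": "none", "threshold": 6.5},
    {"max_age": 65, "complications": null, "threshold": 7.0},
    {"max_age": null, "complications": null, "threshold": 7.5}
  ]
}
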