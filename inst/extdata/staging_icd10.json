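{
  "retinopathy": ["H360", "E103", "E113"],
  "cerebrovascular": ["I63", "I64", "I69", "G45"],
  "ckd": ["N18", "E112"]
}
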