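# Default synthetic-cohort configuration. Omitted fields (initial stage
# probabilities, transition matrices, biomarker moments, prevalences) use the
# package defaults, which reproduce the published per-stage baseline
# characteristics and transition structure of the reference cohort.
n_patients: 2000
years: [2018, 2019, 2020]
seed: 1
render_notes: true
note_noise:
  misspelling_rate: 0.0
  abbreviation_rate: 0.25
  distractor_rate: 0.3
structured_drug_missing_rate: 0.3
hba1c_missing_rate: 0.0
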