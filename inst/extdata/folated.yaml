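groups:
- folate
- placebo
ratio:
- 1
- 1
variables:
  center:
  - Bangor
  - Swansea
  - Wrexham
  gender:
  - female
  - male
  patient_type:
  - new/counselling
  - new/no-counselling
  - continuing/counselling
  - continuing/no-counselling
  antidepressant:
  - SSRI
  - other
weights:
  overall: 0.02
  variables:
    center: 0.04
    gender: 0.04
    patient_type: 0.02
    antidepressant: 0.02
  stratum: 0.05
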