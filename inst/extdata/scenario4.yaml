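groups:
- A
- B
ratio:
- 1
- 1
variables:
  center:
  - X
  - 'Y'
  - Z
  gender:
  - M
  - F
weights:
  overall: 0.0
  variables:
    center: 0.0
    gender: 0.0
  stratum: 0.0
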