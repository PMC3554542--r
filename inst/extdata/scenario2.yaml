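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
  overall: 0.10000000000000001
  variables:
    center: 0.20000000000000001
    gender: 0.20000000000000001
  stratum: 0.5
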