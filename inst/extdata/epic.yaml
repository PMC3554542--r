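groups:
- intervention
- control
ratio:
- 2
- 1
variables:
  age:
  - 6-10
  - 11-15
  - 16-18
  gender:
  - female
  - male
  diagnosis:
  - <2y
  - '>=2y'
  center:
  - C1
  - C2
  - C3
  - C4
weights:
  overall: 0.05
  variables:
    age: 0.05
    gender: 0.05
    diagnosis: 0.05
    center: 0.10000000000000001
  stratum: 0.20000000000000001
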