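groups:
- MBCT
- CPE
- TAU
ratio:
- 2
- 2
- 1
variables:
  center:
  - Oxford
  - Bangor
  cohort:
  - cohort1
  - cohort2
  - cohort3
  - cohort4
  - cohort5
  - cohort6
  suicidality:
  - none
  - ideation
  - attempt
  ad_use:
  - 'no'
  - 'yes'
weights:
  overall: 0.05
  variables:
    center: 0.10000000000000001
    cohort: 0.10000000000000001
    suicidality: 0.05
    ad_use: 0.05
  stratum: 0.25
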