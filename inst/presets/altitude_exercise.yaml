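schema_version: 1
name: altitude_exercise
species: human
body_mass: 70
duration_s: 600
environment:
- t: 0
  FiO2: 0.1185
  P_B: 429
workload:
- t: 0
  work: 0
- t: 120
  work: 60
- t: 240
  work: 120
- t: 360
  work: 180
- t: 480
  work: 240
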