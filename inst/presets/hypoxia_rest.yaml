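schema_version: 1
name: hypoxia_rest
species: human
body_mass: 70
duration_s: 900
isocapnic: true
environment:
- t: 0
- t: 60
  FiO2: 0.09
- t: 660
  FiO2: 0.2093
workload:
- t: 0
  work: 0
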