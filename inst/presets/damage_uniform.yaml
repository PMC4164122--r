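schema_version: 1
name: damage_uniform
species: human
body_mass: 70
duration_s: 600
damage:
  uniform: 0.20
  k_w: 0.25
workload:
- t: 0
  work: 360
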