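schema_version: 1
name: rest
species: human
body_mass: 70
duration_s: 180
environment:
- t: 0
workload:
- t: 0
  work: 0
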