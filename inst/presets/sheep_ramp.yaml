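schema_version: 1
name: sheep_ramp
species: sheep
body_mass: 40
duration_s: 1800
treadmill:
  protocol: sheep_ramp
  grade: 9
  c_level: 1.5
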