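# Example configuration: reference parameters, 400 mm square arena,
# one-hour contact-induced-asymmetry exploration.
modulation_strength: 0.5
noise_gain: 0.025
obstacles:
- cx_mm: 200.0
  cy_mm: -10.0
  width_mm: 440.0
  height_mm: 20.0
  angle_deg: 0.0
- cx_mm: 200.0
  cy_mm: 410.0
  width_mm: 440.0
  height_mm: 20.0
  angle_deg: 0.0
- cx_mm: -10.0
  cy_mm: 200.0
  width_mm: 20.0
  height_mm: 440.0
  angle_deg: 0.0
- cx_mm: 410.0
  cy_mm: 200.0
  width_mm: 20.0
  height_mm: 440.0
  angle_deg: 0.0
experiment:
  name: cia
  duration_s: 3600
  seed: 1
  n_trials: 1
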