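# Pea cultivar Lucy: semi-leafless, hr type, low developmental rate.
name: Lucy
leaf_type: semi-leafless
maturity_dd: 1565
schnute: {A: 1.89e-3, B: 0.39, y_max: 24.8, t_max: 1565}
expansion_dd: 75
basal_offset_mm: 25
stem_width_mm: 2.7
internode_profile:
  scale_mm: 40
  r: [0.0, 0.25, 0.5, 0.8, 1.0]
  m: [0.80, 0.90, 1.00, 1.00, 0.85]
stipule_profile: {base_mm: 20, peak_mm: 50, peak_from: 0.6, peak_to: 0.8, tip_mm: 30}
inclination_dynamics:
  stipule: {t: [300, 600, 1240], deg: [44.5, 43.3, 48.7]}
branching:
  insertion: basal
  stages:
    - {from_dd: 1240, min: 0, max: 1, phytomers: [3.0], sd: [0.5]}
area_contributions: {stipules: 0.91, leaflets: 0.0, stems: 0.09}
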