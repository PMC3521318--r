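# Pea cultivar James: semi-leafless, hr type, early maximal rate.
name: James
leaf_type: semi-leafless
maturity_dd: 1445
schnute: {A: 1.94e-3, B: 0.49, y_max: 25.6, t_max: 1445}
expansion_dd: 75
basal_offset_mm: 25
stem_width_mm: 2.2
leaf_scale: 0.85
internode_profile:
  scale_mm: 35
  r: [0.0, 0.25, 0.5, 0.8, 1.0]
  m: [0.80, 0.90, 1.00, 1.00, 0.85]
stipule_profile: {base_mm: 20, peak_mm: 50, peak_from: 0.6, peak_to: 0.8, tip_mm: 30}
inclination_dynamics:
  stipule: {t: [300, 600, 1240], deg: [38.0, 39.3, 45.2]}
branching:
  insertion: basal
  stages:
    - {from_dd: 300, min: 0, max: 1, phytomers: [3.0], sd: [0.3]}
    - {from_dd: 600, min: 0, max: 1, phytomers: [5.7], sd: [2.0]}
    - {from_dd: 1240, min: 0, max: 1, phytomers: [6.0], sd: [2.2]}
area_contributions: {stipules: 0.89, leaflets: 0.0, stems: 0.11}
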