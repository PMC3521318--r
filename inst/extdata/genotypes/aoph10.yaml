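# Pea cultivar AOPH10: semi-leafless, late hr type, long phytomer production.
name: AOPH10
leaf_type: semi-leafless
maturity_dd: 1630
schnute: {A: 1.18e-3, B: 0.57, y_max: 32.9, t_max: 1630}
expansion_dd: 75
basal_offset_mm: 25
stem_width_mm: 2.7
leaf_scale: 0.87
internode_profile:
  scale_mm: 30
  r: [0.0, 0.25, 0.5, 0.8, 1.0]
  m: [0.80, 0.90, 1.00, 1.00, 0.85]
stipule_profile: {base_mm: 20, peak_mm: 50, peak_from: 0.6, peak_to: 0.8, tip_mm: 30}
inclination_dynamics:
  stipule: {t: [300, 600, 1240, 1560], deg: [37.8, 38.7, 49.7, 49.8]}
branching:
  insertion: basal
  stages:
    - {from_dd: 300, min: 0, max: 1, phytomers: [3.0], sd: [0.3]}
    - {from_dd: 600, min: 0, max: 2, phytomers: [9.5, 5.0], sd: [0.5, 0.5]}
    - {from_dd: 1240, min: 0, max: 2, phytomers: [22.8, 6.0], sd: [1.3, 0.5]}
    - {from_dd: 1560, min: 0, max: 1, phytomers: [25.7], sd: [1.5]}
area_contributions: {stipules: 0.91, leaflets: 0.0, stems: 0.09}
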