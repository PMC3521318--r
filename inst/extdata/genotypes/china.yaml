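# Pea cultivar China: leafy, hr type, earliest development.
name: China
leaf_type: leafy
maturity_dd: 1310
schnute: {A: 2.14e-3, B: 0.47, y_max: 20.6, t_max: 1310}
expansion_dd: 75
basal_offset_mm: 25
stem_width_mm: 2.5
leaf_scale: 0.95
leaflet_pairs: 1
internode_profile:
  scale_mm: 73
  r: [0.0, 0.25, 0.5, 0.8, 1.0]
  m: [0.40, 0.60, 1.00, 1.05, 0.85]
stipule_profile: {base_mm: 17, peak_mm: 50, peak_from: 0.6, peak_to: 0.8, tip_mm: 28}
leaflet_profile: {base_mm: 15, peak_mm: 45, peak_pos: 0.5, tip_mm: 27}
inclination_dynamics:
  stipule: {t: [300, 600, 1240], deg: [23.6, 36.6, 45.9]}
  leaflet: {t: [200, 1310], deg: [16.0, 37.0]}
branching:
  insertion: [12, 14]   # branches mainly initiated between the 12th and 14th phytomer
  stages:
    - {from_dd: 600, min: 0, max: 1, phytomers: [2.5], sd: [0.5]}
    - {from_dd: 1240, min: 0, max: 1, phytomers: [2.8], sd: [0.4]}
area_contributions: {stipules: 0.47, leaflets: 0.45, stems: 0.08}
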