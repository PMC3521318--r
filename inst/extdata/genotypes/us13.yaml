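# Pea cultivar US13: leafy, hr type.
name: US13
leaf_type: leafy
maturity_dd: 1445
schnute: {A: 1.89e-3, B: 0.44, y_max: 24.6, t_max: 1445}
expansion_dd: 75
basal_offset_mm: 25
stem_width_mm: 2.4
leaf_scale: 1.08
leaflet_pairs: 2
internode_profile:
  scale_mm: 47
  r: [0.0, 0.25, 0.5, 0.8, 1.0]
  m: [0.55, 0.75, 1.00, 1.05, 0.85]
stipule_profile: {base_mm: 20, peak_mm: 50, peak_from: 0.6, peak_to: 0.8, tip_mm: 30}
leaflet_profile: {base_mm: 11.3, peak_mm: 31.8, peak_pos: 0.5, tip_mm: 17.0}
inclination_dynamics:
  stipule: {t: [300, 600, 1240], deg: [47.9, 43.7, 60.5]}
  leaflet: {t: [200, 1445], deg: [16.0, 37.0]}
branching:
  insertion: basal
  stages:
    - {from_dd: 1240, min: 0, max: 1, phytomers: [8.0], sd: [0.5]}
area_contributions: {stipules: 0.46, leaflets: 0.49, stems: 0.05}
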