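# Pea cultivar 886/01: semi-leafless, HR (photoperiod-responsive), latest and
# most branching cultivar.
name: "886/01"
leaf_type: semi-leafless
maturity_dd: 1890
schnute: {A: 0.80e-3, B: 0.65, y_max: 37.6, t_max: 1890}
expansion_dd: 75
basal_offset_mm: 25
stem_width_mm: 2.7
internode_profile:
  scale_mm: 27.5
  r: [0.0, 0.25, 0.5, 0.8, 1.0]
  m: [0.80, 0.90, 1.00, 1.00, 0.85]
stipule_profile: {base_mm: 20, peak_mm: 50, peak_from: 0.6, peak_to: 0.8, tip_mm: 30}
inclination_dynamics:
  stipule: {t: [300, 600, 1240, 1560], deg: [41.7, 38.6, 51.1, 55.0]}
branching:
  insertion: basal
  stages:
    - {from_dd: 600, min: 0, max: 2, phytomers: [7.4, 3.7], sd: [1.9, 0.7]}
    - {from_dd: 1240, min: 1, max: 3, phytomers: [18.6, 14.2, 10.0], sd: [4.1, 2.0, 2.3]}
    - {from_dd: 1560, min: 1, max: 3, phytomers: [23.5, 16.9, 12.4], sd: [3.8, 6.4, 5.1]}
area_contributions: {stipules: 0.91, leaflets: 0.0, stems: 0.09}
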