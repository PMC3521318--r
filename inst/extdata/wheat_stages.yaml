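# Wheat (cv. Caphorn) stand descriptors per simulated stage: green LAI at the
# reference density, plant height and area-weighted blade inclination.
cultivar: Caphorn
density: 125
stages:
  - {dd: 300, lai: 0.13, height_m: 0.113, inclination_deg: 65.5}
  - {dd: 600, lai: 0.83, height_m: 0.160, inclination_deg: 67.0}
  - {dd: 1240, lai: 1.00, height_m: 0.652, inclination_deg: 64.3}
  - {dd: 1560, lai: 0.46, height_m: 0.691, inclination_deg: 61.0}
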