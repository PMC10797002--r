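# SYNTHETIC seed-definition example (2 mm spheres on a template grid).
# These are stand-in coordinates for demonstration and tests only; they are
# NOT the seed coordinates of any published atlas or study.
grid:
  dim: [64, 64, 40]
  spacing_mm: 1.0
seeds:
  - {name: M1_med,   center: [22, 40, 28], radius: 2}
  - {name: M1_lat,   center: [30, 42, 26], radius: 2}
  - {name: S1,       center: [24, 36, 27], radius: 2}
  - {name: S2,       center: [34, 30, 18], radius: 2}
  - {name: F4_d,     center: [28, 46, 22], radius: 2}
  - {name: F4_v,     center: [30, 46, 18], radius: 2}
  - {name: F5c_med,  center: [26, 48, 20], radius: 2}
  - {name: F5c_lat,  center: [31, 48, 17], radius: 2}
  - {name: F5p,      center: [27, 45, 21], radius: 2}
  - {name: F5a,      center: [29, 50, 19], radius: 2}
  - {name: PF,       center: [38, 26, 24], radius: 2}
  - {name: PFG,      center: [40, 24, 26], radius: 2}
  - {name: AIP,      center: [36, 28, 25], radius: 2}
  - {name: DO,       center: [30, 44, 14], radius: 2}
  - {name: PrCO,     center: [32, 42, 15], radius: 2}
  - {name: GrFO,     center: [33, 46, 12], radius: 2}
  - {name: area12o,  center: [24, 54, 10], radius: 2}
  - {name: area12r,  center: [22, 56, 12], radius: 2}
  - {name: FST,      center: [42, 20, 16], radius: 2}
  - {name: MT,       center: [44, 18, 18], radius: 2}
  - {name: amygdala, center: [28, 34, 10], radius: 2}
  - {name: ext_a,    center: [20, 30, 20], radius: 2}
  - {name: ext_b,    center: [46, 32, 22], radius: 2}
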