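# Three-shot plugged plan in a 16 cm spherical phantom, 8 Gy prescribed to
# the 50% isodose (16 Gy maximum). Shot positions, collimators and plugged
# channel counts follow the experimental plan; the plug sectors are a
# synthetic stand-in: one azimuthal wedge per shot whose angular width is
# 360 * n_plugs / 201 degrees, oriented toward the flanking organs at risk.
prescription_dose_gy: 8.0
prescription_isodose: 0.5
phantom_radius_mm: 80.0
phantom_center_mm: [100.0, 100.0, 100.0]
shots:
  - isocenter_mm: [102.0, 84.0, 103.0]
    collimator_mm: 18
    weight: 1.0
    # 45 of 201 channels plugged -> 80.6 degree wedge toward +X
    plugs:
      - {azimuth_start_deg: 319.7, azimuth_end_deg: 360.0, transmission: 0.0}
      - {azimuth_start_deg: 0.0, azimuth_end_deg: 40.3, transmission: 0.0}
  - isocenter_mm: [101.0, 110.0, 101.0]
    collimator_mm: 14
    weight: 1.0
    # 21 of 201 channels plugged -> 37.6 degree wedge toward -X
    plugs:
      - {azimuth_start_deg: 161.2, azimuth_end_deg: 198.8, transmission: 0.0}
  - isocenter_mm: [76.0, 95.5, 106.5]
    collimator_mm: 8
    weight: 1.0
    # 46 of 201 channels plugged -> 82.4 degree wedge toward -X
    plugs:
      - {azimuth_start_deg: 138.8, azimuth_end_deg: 221.2, transmission: 0.0}
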