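# Default QA pipeline configuration (mirrors default_qa_config()).
# Units: doses in Gy, lengths in mm, echo times in ms, rates in Gy/min.
seed: 1
threshold_pct: 5.0          # FWHM deviation pass limit, percent
te_pair: [89.0, 145.0]      # dual-echo readout
grid:
  shape: [13, 81, 81]       # sagittal-style: 2.5 mm slices, 0.5 mm in-plane
  spacing: [2.5, 0.5, 0.5]
  center: [100.0, 100.0, 100.0]
shots:                      # one 4 Gy@50% shot per collimator
  - {collimator: 4, prescription_dose: 4.0}
  - {collimator: 8, prescription_dose: 4.0}
  - {collimator: 16, prescription_dose: 4.0}
gel:
  r2_baseline: 8.0          # s^-1 at zero dose (T2 = 125 ms)
  sensitivity: 0.084        # normalized-R2 slope, Gy^-1
  saturation_dose: 400.0    # Gy scale of the saturating regime
  s0: 1000.0
  noise_sigma: 0.0          # Rician magnitude-noise SD, signal units
film:
  od_saturation: 0.5        # maximum net OD
  dose_scale: 5.0           # Gy; low-dose slope = od_saturation / dose_scale
  pv0: 40000.0              # unexposed pixel value, 16-bit scale
  noise_sigma: 0.0
calibration:
  doses: [0, 2, 4, 6, 8, 10, 12, 16]
  linear_max_dose: 16
profile:
  axis: z
  denominator: reference    # reference | measured | both
film_scan:
  dpi: 1200
  region_mm: 24
similarity:
  levels: [90, 80, 70, 60, 50, 30, 10]
  window: 11
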