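version: '1'
hic:
  shape: 4.34
  scale: 671.0
  citation: Funk et al. 2007 mTBI Weibull fit
bric:
  shape: 2.84
  scales:
  - .na.real
  - .na.real
  - .na.real
  - .na.real
  critical:
  - 66.3
  - 53.8
  - 41.5
  citation: Takhounts et al. BrIC; per-level scales unpublished
neck_tension:
  cut_points:
  - 6.3
  - 8.56
  - 9.28
  - 10.19
  slope: 0.0053
  citation: Philippens et al. PMHS ordered probit
neck_compression:
  beta0: 934.2
  beta1: 8.9
  beta2: 11.0
  beta3: 665.0
  beta4: -0.134
  beta5: .na.real
  age: 52.0
  loading_rate: 2.0
  gender: 0.0
  citation: Pintar et al. tolerance model; beta5 unpublished
chest:
  cut_points:
  - 4.17
  - 5.61
  - 6.29
  - 7.32
  slope: 0.103
  citation: Mertz sternal-compression reanalysis
fmvss_chest:
  intercepts:
  - 1.8706
  - 3.7124
  - 5.0952
  - 8.8274
  slopes:
  - 0.04439
  - 0.0475
  - 0.0475
  - 0.0459
  levels:
  - 2
  - 3
  - 4
  - 5
  citation: NHTSA FMVSS 208
ncap_chest:
  coefficients:
  - 12.597
  - 0.05861
  - 1.568
  - 0.4612
  citation: NHTSA NCAP age-dependent chest risk
shoulder:
  intercept: 8.14
  age_slope: 0.0055
  shape: 7.41
  transfer: 2.016
  age: 56.0
  citation: Petitjean et al. WorldSID risk x THOR transfer; eldest male astronaut
acetabular:
  intercept: 6.403
  slope: 0.0011
  citation: Kuppa EuroSID pelvic risk on the THOR scale
eurosid_pelvis:
  intercept: 6.403
  slope: 0.00163
  citation: Kuppa EuroSID-2re pelvic risk
thoracic_spine:
  risk_slope: 3.73
  risk_intercept: 15.8
  dri_gain: 3.62
  dri_offset: -2.59
  force_gain: 0.277
  force_offset: 0.795
  citation: DRI ejection-data fit + THOR spine regression
dorsiflexion:
  location: 60.23
  scale: 9.217
  citation: Kuppa et al. ankle dorsiflexion
inversion_eversion:
  cut: 4.0
  slope: 0.1
  citation: Kuppa et al. ankle inversion/eversion (digitized)
adfs:
  pmhs_intercept: 6.749
  thor_intercept: 9.845
  slope: 0.645
  mass_slope: 1.94
  reference_mass: 2.67
  thor_arm_mass: 4.27
  citation: Hardy et al. ADFS fits + arm-mass scaling
forearm:
  bass:
    location: 66.2
    scale: 15.0
  duma:
    location: 58.0
    scale: 6.62
  citation: Bass / Duma forearm moment fits
acceptable_risk:
  nominal:
  - 0.05
  - 0.01
  - 0.003
  - 0.0003
  off_nominal:
  - 0.19
  - 0.04
  - 0.01
  - 0.001
  citation: NASA definition of acceptable risk, class I-IV
deconditioning:
  none: 1.0
  spine: 0.86
  lower_extremity: 0.75
  citation: NASA spaceflight deconditioning factors
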