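# Canonical simulation settings shipped with postDCA, resolved to numeric
# parameters. Generated from binary_sim_settings() / survival_sim_settings();
# a package test asserts this file stays in sync with those functions.
binary:
- id: binary_auc065_prev01
  max_auc: 0.65
  prevalence: 0.01
  beta:
  - -4.75
  - -0.405465108108164
  - 0.405465108108164
  beta_hat:
  - -5.0
  - -0.506831385135206
  - 0.506831385135206
- id: binary_auc065_prev05
  max_auc: 0.65
  prevalence: 0.05
  beta:
  - -3.1
  - -0.405465108108164
  - 0.405465108108164
  beta_hat:
  - -3.9
  - -1.216395324324493
  - 1.216395324324493
- id: binary_auc065_prev30
  max_auc: 0.65
  prevalence: 0.3
  beta:
  - -0.9
  - -0.438254930931155
  - 0.438254930931155
  beta_hat:
  - -1.2
  - -1.314764792793466
  - 1.314764792793466
- id: binary_auc085_prev01
  max_auc: 0.85
  prevalence: 0.01
  beta:
  - -5.6
  - -0.943905898907128
  - 0.943905898907128
  beta_hat:
  - -6.9
  - -1.415858848360693
  - 1.415858848360693
- id: binary_auc085_prev05
  max_auc: 0.85
  prevalence: 0.05
  beta:
  - -3.755
  - -1.081805170351728
  - 1.081805170351728
  beta_hat:
  - -7.3
  - -3.245415511055185
  - 3.245415511055185
- id: binary_auc085_prev30
  max_auc: 0.85
  prevalence: 0.3
  beta:
  - -1.3
  - -1.504077396776274
  - 1.504077396776274
  beta_hat:
  - -2.25
  - -4.512232190328822
  - 4.512232190328822
survival:
- id: surv_c060_s10
  max_cstat: 0.6
  surv1yr: 0.1
  gamma: 1.22
  lambda: 0.12
  beta:
  - 0.262364264467491
  - -0.356674943938732
  beta_hat:
  - 0.264987907112166
  - -0.36024169337812
  censor_max: 24.0
  horizon: 12.0
- id: surv_c060_s20
  max_cstat: 0.6
  surv1yr: 0.2
  gamma: 1.07
  lambda: 0.12
  beta:
  - 0.262364264467491
  - -0.356674943938732
  beta_hat:
  - 0.264987907112166
  - -0.36024169337812
  censor_max: 24.0
  horizon: 12.0
- id: surv_c060_s50
  max_cstat: 0.6
  surv1yr: 0.5
  gamma: 0.7
  lambda: 0.12
  beta:
  - 0.262364264467491
  - -0.356674943938732
  beta_hat:
  - 0.264987907112166
  - -0.36024169337812
  censor_max: 24.0
  horizon: 12.0
- id: surv_c090_s10
  max_cstat: 0.9
  surv1yr: 0.1
  gamma: 4.6
  lambda: 0.0004
  beta:
  - 0.667829372575655
  - -2.995732273553991
  beta_hat:
  - 0.834786715719569
  - -3.744665341942488
  censor_max: 24.0
  horizon: 12.0
- id: surv_c090_s20
  max_cstat: 0.9
  surv1yr: 0.2
  gamma: 4.0
  lambda: 0.0004
  beta:
  - 0.667829372575655
  - -2.995732273553991
  beta_hat:
  - 0.834786715719569
  - -3.744665341942488
  censor_max: 24.0
  horizon: 12.0
- id: surv_c090_s50
  max_cstat: 0.9
  surv1yr: 0.5
  gamma: 2.9
  lambda: 0.0004
  beta:
  - 0.667829372575655
  - -2.995732273553991
  beta_hat:
  - 0.834786715719569
  - -3.744665341942488
  censor_max: 24.0
  horizon: 12.0
- id: surv_c095_s10
  max_cstat: 0.95
  surv1yr: 0.1
  gamma: 6.5
  lambda: 0.0004
  beta:
  - 0.667829372575655
  - -6.907755278982137
  beta_hat:
  - 0.834786715719569
  - -8.634694098727671
  censor_max: 24.0
  horizon: 12.0
- id: surv_c095_s20
  max_cstat: 0.95
  surv1yr: 0.2
  gamma: 5.4
  lambda: 0.0004
  beta:
  - 0.667829372575655
  - -6.907755278982137
  beta_hat:
  - 0.834786715719569
  - -8.634694098727671
  censor_max: 24.0
  horizon: 12.0
- id: surv_c095_s50
  max_cstat: 0.95
  surv1yr: 0.5
  gamma: 3.1
  lambda: 0.0004
  beta:
  - 0.667829372575655
  - -6.907755278982137
  beta_hat:
  - 0.834786715719569
  - -8.634694098727671
  censor_max: 24.0
  horizon: 12.0

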