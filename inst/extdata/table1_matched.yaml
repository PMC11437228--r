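# Synthetic cohort spec encoding the study-population margins:
# matched-cohort covariate prevalences, per-period service-utilization and
# 30-day outcome rates, full-cohort arm sizes, and mild secular confounding
# of the size seen in the unmatched arms.
n_pre: 13365
n_post: 12119
cutover: "2022-07-01"
study_start: "2021-07-01"
study_end: "2023-06-30"
covariates:
  sex_male: 0.438
  hispanic: 0.119
  afib: 0.081
  cad: 0.104
  chf: 0.033
  cva_tia: 0.040
  ckd: 0.102
  diabetes: 0.201
  mets_lt4: 0.146
  asa_3or4: 0.350
  rcri_component: 0.067
  mica_elevated: 0.050
  race:
    Asian: 0.012
    African American: 0.079
    White: 0.792
    American Indian: 0.004
    Others: 0.113
  surgical_risk:
    low: 0.232
    moderate: 0.558
    high: 0.210
flags:
  active_cardiac_condition: 0.005
  cardiac_disease_unclear_status: 0.020
  ischemia_concern: 0.020
  ecg_flag: 0.030
  testing_may_change_management: 0.500
confounding_strength:
  sex_male: 0.05
  race_White: 0.10
  afib: 0.09
  cad: 0.10
  ckd: 0.13
  mets_lt4: 0.14
  surgical_risk_high: 0.12
service_rates:
  consult: {pre: 0.232, post: 0.179}
  echo: {pre: 0.069, post: 0.051}
  stress: {pre: 0.0170, post: 0.0155}
  cath: {pre: 0.0045, post: 0.0038}
outcome_rates:
  mi: {pre: 0.0012, post: 0.0012}
  revasc: {pre: 0.0002, post: 0.0004}
  chf_acute: {pre: 0.0019, post: 0.0021}
  death: {pre: 0.0014, post: 0.0014}
  icu: {pre: 0.0145, post: 0.0157}
  ed_visit: {pre: 0.058, post: 0.054}
  readmission: {pre: 0.064, post: 0.065}
age:
  mean: 63.5
  sd: 13.5
  min: 18
  max: 95
noise:
  service_out_of_window: 0.01
  outcome_late: 0.005
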