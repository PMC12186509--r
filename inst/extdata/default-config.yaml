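# Reference run configuration; every value reproduces the base case.
costs:
  daily_variable: 2945     # USD per inpatient bed-day (variable costs only)
  staffing: 518000         # USD/year, 2.0 FTE RN + 0.5 FTE hospitalist
  dme: 164547              # USD/year, durable medical equipment
rates:                     # local contracting facts; see calibrate_cohort_spec()
  medicare:
    base_payment_rate: 12000
    dsh_addon: 1500
    per_diem: 1530
  medicaid:
    per_diem: 625
  commercial:
    flat_daily_rate: 7800
  tricare_va:
    flat_daily_rate: 2100
mixes:
  la_general: {commercial: 0.016, medicare: 0.138, medicaid: 0.772, uninsured: 0.074}
  typical_us: {commercial: 0.45, medicare: 0.35, medicaid: 0.10, uninsured: 0.10}
  half_commercial_triple_medicaid: {commercial: 0.225, medicare: 0.175, medicaid: 0.40, uninsured: 0.20}
neutrality_weights: {commercial: 1.0, medicare: 1.0, medicaid: 0.5, uninsured: 0.0}
payer_model:
  split_difference: 5000   # hospital billing minus lost productivity, USD
  hosp_reduction: 0.75
  wage_recovery: 0.30
  qol_hospital: 0.7
  qol_home: 0.9
  reimbursement: 15000
  total_cost_grid: [20000, 25000, 30000, 35000, 40000, 45000]
scenario:
  n_total: 1000
  scale_grid: [0.5, 0.75, 1.0, 1.25, 1.5]
cohort:
  n_patients: 876
  mean_days_saved: 4
  sd_days: 2
  drg_weight_mean: 1.27
  drg_weight_sd: 0.66
  avoid_prob: 0.55
  urgent_care_rate: 0.61
seed: 20220901
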