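# Reference parameter set: 55-year-old post-mastectomy cohort, 15-year
# horizon, payer perspective. Probabilities are stored exactly as published
# (scale: percent); load_parameters() converts them to fractions.
#
# Conventions:
#   - period_cumulative: the value is the total probability over the band;
#     the per-cycle probability is value / band length.
#   - annual: the value is applied unchanged in every cycle of the band
#     (the metastasis-to-death rows are published annual mortality rates).
#   - Published year labels "0-5" / "6-10" / "11-15" map to cycles 1-5 /
#     6-10 / 11-15; normal-death age bands 56-60 / 61-65 / 66-70 map to the
#     same cycles for the age-55 cohort.
settings:
  discount_rate: 0.03
  horizon: 15
  start_age: 55
  cycle_length: 1
  half_cycle: false
  recurrence_progression: false
  windows:
    cardiac: [11, 15]
    lung: [11, 15]
    cl_breast: [6, 15]
strategies:
  - name: SOC
    rt_cost: 12140
    p_cardiac: {base: 5.84, scale: percent}
    p_cl_breast: {base: 1.0, scale: percent}
    p_lung: {base: 4.4, scale: percent}
  - name: STD-VMAT
    rt_cost: 17438
    p_cardiac: {base: 0.97, low: 0.05, high: 2.54, scale: percent}
    p_cl_breast: {base: 0.11, low: 0.06, high: 0.23, scale: percent}
    p_lung: {base: 0.63, low: 0.08, high: 0.95, scale: percent}
  - name: TOMO
    rt_cost: 17438
    p_cardiac: {base: 0.98, low: 0.07, high: 2.39, scale: percent}
    p_cl_breast: {base: 0.10, low: 0.06, high: 0.22, scale: percent}
    p_lung: {base: 0.72, low: 0.11, high: 1.18, scale: percent}
  - name: IMRT
    rt_cost: 17438
    p_cardiac: {base: 0.95, low: 0.05, high: 2.58, scale: percent}
    p_cl_breast: {base: 0.04, low: 0.02, high: 0.06, scale: percent}
    p_lung: {base: 0.57, low: 0.08, high: 0.84, scale: percent}
  - name: MA-VMAT
    rt_cost: 17438
    p_cardiac: {base: 0.89, low: 0.05, high: 2.31, scale: percent}
    p_cl_breast: {base: 0.09, low: 0.04, high: 0.20, scale: percent}
    p_lung: {base: 0.55, low: 0.07, high: 0.92, scale: percent}
  - name: NC-VMAT
    rt_cost: 17438
    p_cardiac: {base: 0.89, low: 0.05, high: 2.34, scale: percent}
    p_cl_breast: {base: 0.08, low: 0.02, high: 0.20, scale: percent}
    p_lung: {base: 0.54, low: 0.07, high: 0.89, scale: percent}
  - name: MIXED
    rt_cost: 19715
    p_cardiac: {base: 0.86, low: 0.05, high: 2.22, scale: percent}
    p_cl_breast: {base: 0.07, low: 0.03, high: 0.15, scale: percent}
    p_lung: {base: 0.63, low: 0.08, high: 1.01, scale: percent}
  - name: IMPT
    rt_cost: 33547
    p_cardiac: {base: 0.40, low: 0.04, high: 0.84, scale: percent}
    p_cl_breast: {base: 0.003, low: 0.00, high: 0.007, scale: percent}
    p_lung: {base: 0.22, low: 0.03, high: 0.60, scale: percent}
disease:
  local_recurrence:
    bands:
      - {start: 1, end: 5, value: 6.5, scale: percent, convention: period_cumulative}
      - {start: 6, end: 10, value: 1.84, scale: percent, convention: period_cumulative}
      - {start: 11, end: 15, value: 0.325, scale: percent, convention: period_cumulative}
  metastasis:
    bands:
      - {start: 1, end: 5, value: 18.1, scale: percent, convention: period_cumulative}
      - {start: 6, end: 10, value: 9.2, scale: percent, convention: period_cumulative}
      - {start: 11, end: 15, value: 5.68, scale: percent, convention: period_cumulative}
  metastasis_death:
    bands:
      - {start: 1, end: 5, value: 25.9, scale: percent, convention: annual}
      - {start: 6, end: 15, value: 15.6, scale: percent, convention: annual}
mortality:
  background:
    bands:
      - {start: 1, end: 5, value: 3.2, scale: percent, convention: period_cumulative}
      - {start: 6, end: 10, value: 4.7, scale: percent, convention: period_cumulative}
      - {start: 11, end: 15, value: 5.8, scale: percent, convention: period_cumulative}
  lung:
    bands:
      - {start: 11, end: 15, value: 0.49, scale: percent, convention: period_cumulative}
  heart:
    bands:
      - {start: 11, end: 15, value: 2.6, scale: percent, convention: period_cumulative}
  cl_breast:
    bands:
      - {start: 11, end: 15, value: 21.7, scale: percent, convention: period_cumulative}
utilities:
  ned: {base: 1.0}
  recurrence: {base: 0.85}
  metastasis: {base: 0.62}
  cardiac: {base: 0.85, low: 0.8, high: 0.9}
  cl_breast: {base: 0.803, low: 0.708, high: 0.816}
  lung: {base: 0.72, low: 0.57, high: 0.87}
costs:
  recurrence: {base: 20879}
  metastasis: {base: 13627}
  cardiac: {base: 11570, low: 8165, high: 14975}
  cl_breast: {base: 14494, low: 13295, high: 15693}
  lung: {base: 20577, low: 17837, high: 23317}
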