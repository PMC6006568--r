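# Bundled study configuration: brief substance-use interventions delivered
# by lay counsellors in three Western Cape emergency departments, 2012/13
# prices, costs in USD (converted at ZAR 10.3952 per US$1).
study: strive
currency: USD
zar_per_usd: 10.3952
discount_rate: 0.03

# Ingredients ledger. Capital rows are entered as printed annual
# (pre-annuitized) figures; raw purchase prices may instead be entered with
# cost_form: raw-capital plus useful_life_years.
ledger:
  - {item: supervisor_direct_support, cost_class: variable, basis: lump,
     qty_per_basis: 1, unit_cost: 562.76, cost_form: lump-sum,
     allocation: time_share}
  - {item: supervisor_fidelity_checks, cost_class: variable, basis: lump,
     qty_per_basis: 1, unit_cost: 25973.53, cost_form: lump-sum,
     allocation: time_share}
  - {item: screening_tool, cost_class: variable, basis: screened,
     qty_per_basis: 1, unit_cost: 0.10, cost_form: unit-price,
     allocation: screening}
  - {item: substance_misuse_flyer, cost_class: variable, basis: accepted,
     qty_per_basis: 1, unit_cost: 0.08, cost_form: unit-price,
     allocation: arms}
  - {item: mi_manual, cost_class: variable, basis: mi_recipients,
     qty_per_basis: 1, unit_cost: 0.34, cost_form: unit-price,
     allocation: mi_arms}
  - {item: pst_manual, cost_class: variable, basis: mi_pst,
     qty_per_basis: 1, unit_cost: 2.00, cost_form: unit-price,
     allocation: mi_pst}
  - {item: counsellors, cost_class: fixed, basis: lump,
     qty_per_basis: 1, unit_cost: 25973.53, cost_form: lump-sum,
     allocation: time_share}
  - {item: pens, cost_class: fixed, basis: counsellor,
     qty_per_basis: 10, unit_cost: 0.46, cost_form: unit-price,
     allocation: time_share}
  - {item: clipboards, cost_class: fixed, basis: counsellor,
     qty_per_basis: 1, unit_cost: 1.54, cost_form: unit-price,
     allocation: time_share}
  - {item: tape_recorders, cost_class: fixed, basis: counsellor,
     qty_per_basis: 1, unit_cost: 115.44, cost_form: unit-price,
     allocation: time_share}
  - {item: tapes, cost_class: fixed, basis: lump,
     qty_per_basis: 1, unit_cost: 346.31, cost_form: lump-sum,
     allocation: time_share}
  - {item: counselling_room, cost_class: fixed, basis: lump,
     qty_per_basis: 1, unit_cost: 220.26, cost_form: pre-annuitized,
     useful_life_years: 20, allocation: time_share}
  - {item: furniture, cost_class: fixed, basis: lump,
     qty_per_basis: 1, unit_cost: 285.08, cost_form: pre-annuitized,
     useful_life_years: 5, allocation: time_share}
  - {item: counsellor_training, cost_class: fixed, basis: lump,
     qty_per_basis: 1, unit_cost: 425.11, cost_form: pre-annuitized,
     useful_life_years: 3, allocation: time_share}

# Counsellor contact time per session type and sessions delivered.
sessions:
  - {component: screening, session_type: screening, minutes_per_patient: 10,
     n_sessions: 2736}
  - {component: mi, session_type: mi, minutes_per_patient: 30,
     n_sessions: 113}
  - {component: mi_pst, session_type: mi, minutes_per_patient: 30,
     n_sessions: 109}
  - {component: mi_pst, session_type: pst1, minutes_per_patient: 60,
     n_sessions: 87}
  - {component: mi_pst, session_type: pst2, minutes_per_patient: 40,
     n_sessions: 77}
  - {component: mi_pst, session_type: pst3, minutes_per_patient: 40,
     n_sessions: 69}
  - {component: mi_pst, session_type: pst4, minutes_per_patient: 40,
     n_sessions: 65}

counts:
  screened: 2736
  positive: 531
  accepted: 332
  n_control: 110
  n_mi: 113
  n_mi_pst: 109
  n_counsellors: 5
  completers_control: 66
  completers_mi: 70
  completers_mi_pst: 46

# MI-PST attendance: participants still attending at the MI session and at
# each of the four weekly PST sessions.
pst_attendance: [109, 87, 77, 69, 65]

capacity:
  available_hours: 4905      # 5 counsellors x 6 h/day over the study period

patient_costs:
  n_interviewed: 48
  mean_cost_per_visit: 0.96
  prop_zero_cost: 0.85
  prop_time_off: 0.08
  prop_income_loss: 0.02

# Per-arm summary outcomes: mean (SD) scale scores among follow-up
# completers at baseline and three months.
effects:
  - {scale: assist, arm: control, baseline_mean: 19.30, baseline_sd: 5.78,
     followup_mean: 11.91, followup_sd: 6.94}
  - {scale: assist, arm: mi, baseline_mean: 19.96, baseline_sd: 6.49,
     followup_mean: 12.28, followup_sd: 6.81}
  - {scale: assist, arm: mi_pst, baseline_mean: 18.71, baseline_sd: 6.32,
     followup_mean: 9.89, followup_sd: 6.64}
  - {scale: cesd, arm: control, baseline_mean: 24.56, baseline_sd: 6.02,
     followup_mean: 20.13, followup_sd: 7.09}
  - {scale: cesd, arm: mi, baseline_mean: 23.93, baseline_sd: 5.43,
     followup_mean: 17.77, followup_sd: 8.12}
  - {scale: cesd, arm: mi_pst, baseline_mean: 27.28, baseline_sd: 8.22,
     followup_mean: 16.64, followup_sd: 8.17}

# Flow probabilities fed to the decision tree. "rounded" reproduces the
# report-rounded convention (0.19, 0.63); "exact" uses the count ratios.
flow_mode: rounded
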