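# Base-case scenario: a UK hospital performing 3,000 cataract operations a
# year, comparing an intracameral mydriatic/anaesthetic injection
# (intervention) with topical tropicamide + phenylephrine eye drops
# (reference).
#
# Per-operation surgeon and theatre times are stored at full precision
# (12.025 / 11.335 min), back-derived from the annual totals they reproduce
# (601.25 h and 566.75 h over 3,000 operations); two-decimal renderings of
# the same inputs are 12.03 / 11.34.
#
# revenue_per_operation is NOT a published input: it is a back-derived
# constant consumed by the configurable throughput-benefit rule.
#
# dsa_bounds stores the one-way sensitivity intervals verbatim, including
# internally odd ones (failure extra time: high 7.5 < base 10.0; adrenaline
# use: low 39% > base 4%). The rescue_distribution entry switches all
# component probabilities to their prob_low / prob_high profiles together.
n_patients: 3000.0
nurse_rate: 43.119999999999997
surgeon_rate: 147.259999999999991
revenue_per_operation: 744.700000000000045
intervention:
  name: intracameral
  p_failure: 0.011
  wait_before_surgery_min: 8.699999999999999
  n_instillation_sessions: 0.0
  session_duration_min: 0.0
  surgeon_working_time_min: 12.025
  or_occupancy_min: 12.025
  extra_time_failure_min: 10.0
  between_op_loss_min: 10.0
  drug_unit_costs:
    mydrane: 6.0
  patients_per_vial: 1.0
reference:
  name: eye_drops
  p_failure: 0.053
  wait_before_surgery_min: 37.899999999999999
  n_instillation_sessions: 3.0
  session_duration_min: 3.0
  surgeon_working_time_min: 11.335000000000001
  or_occupancy_min: 11.335000000000001
  extra_time_failure_min: 10.0
  between_op_loss_min: 10.0
  drug_unit_costs:
    tropicamide: 0.54
    phenylephrine: 0.57
  patients_per_vial: 1.0
rescue:
- component: adrenaline
  prob: 0.04
  cost: 4.95
  prob_low: 0.39
  prob_high: 0.04
- component: phenylephrine
  prob: 0.93
  cost: 0.57
  prob_low: 0.57
  prob_high: 0.93
- component: tropicamide
  prob: 0.14
  cost: 0.54
  prob_low: 0.0
  prob_high: 0.14
- component: mechanical_tools
  prob: 0.04
  cost: 56.799999999999997
  prob_low: 0.05
  prob_high: 0.04
- component: cyclopentolate
  prob: 0.32
  cost: 0.56
  prob_low: 0.01
  prob_high: 0.32
- component: others
  prob: 0.0
  cost: 0.0
  prob_low: 0.0
  prob_high: 0.0
dsa_bounds:
- parameter: p_failure_intracameral
  path:
  - intervention.p_failure
  low: 0.002
  high: 0.032
  type: scalar
- parameter: p_failure_eye_drops
  path:
  - reference.p_failure
  low: 0.03
  high: 0.087
  type: scalar
- parameter: n_instillation_sessions
  path:
  - reference.n_instillation_sessions
  low: 2.0
  high: 4.0
  type: scalar
- parameter: session_duration
  path:
  - reference.session_duration_min
  low: 1.5
  high: 5.0
  type: scalar
- parameter: patients_per_vial
  path:
  - reference.patients_per_vial
  low: 1.0
  high: 5.0
  type: scalar
- parameter: waiting_time_intracameral
  path:
  - intervention.wait_before_surgery_min
  low: 8.19
  high: 9.210000000000001
  type: scalar
- parameter: waiting_time_eye_drops
  path:
  - reference.wait_before_surgery_min
  low: 36.729999999999997
  high: 39.07
  type: scalar
- parameter: nurse_rate
  path:
  - nurse_rate
  low: 35.759999999999998
  high: 59.950000000000003
  type: scalar
- parameter: surgeon_rate
  path:
  - surgeon_rate
  low: 105.180000000000007
  high: 189.330000000000013
  type: scalar
- parameter: surgeon_time_intracameral
  path:
  - intervention.surgeon_working_time_min
  low: 11.51
  high: 12.52
  type: scalar
- parameter: surgeon_time_eye_drops
  path:
  - reference.surgeon_working_time_min
  low: 10.640000000000001
  high: 12.039999999999999
  type: scalar
- parameter: or_occupancy_intracameral
  path:
  - intervention.or_occupancy_min
  low: 11.51
  high: 12.52
  type: scalar
- parameter: or_occupancy_eye_drops
  path:
  - reference.or_occupancy_min
  low: 10.640000000000001
  high: 12.039999999999999
  type: scalar
- parameter: failure_extra_time_intracameral
  path:
  - intervention.extra_time_failure_min
  low: 2.5
  high: 7.5
  type: scalar
- parameter: failure_extra_time_eye_drops
  path:
  - reference.extra_time_failure_min
  low: 2.5
  high: 7.5
  type: scalar
- parameter: between_op_loss_intracameral
  path:
  - intervention.between_op_loss_min
  low: 5.0
  high: 20.0
  type: scalar
- parameter: between_op_loss_eye_drops
  path:
  - reference.between_op_loss_min
  low: 5.0
  high: 20.0
  type: scalar
- parameter: cost_intracameral_product
  path:
  - intervention.drug.mydrane
  low: 3.0
  high: 9.0
  type: scalar
- parameter: cost_adrenaline
  path:
  - rescue.adrenaline.cost
  low: 0.39
  high: 8.31
  type: scalar
- parameter: cost_phenylephrine
  path:
  - reference.drug.phenylephrine
  - rescue.phenylephrine.cost
  low: 0.57
  high: 0.57
  type: scalar
- parameter: cost_tropicamide
  path:
  - reference.drug.tropicamide
  - rescue.tropicamide.cost
  low: 0.5
  high: 1.6
  type: scalar
- parameter: cost_mechanical_tools
  path:
  - rescue.mechanical_tools.cost
  low: 28.399999999999999
  high: 85.200000000000003
  type: scalar
- parameter: cost_cyclopentolate
  path:
  - rescue.cyclopentolate.cost
  low: 0.5
  high: 12.960000000000001
  type: scalar
- parameter: rescue_distribution
  path: []
  low: .na.real
  high: .na.real
  type: mixture
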