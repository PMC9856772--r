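# Six-state monthly Markov model of diabetic foot ulcer care:
# ON101 cream + general wound care (GWC) vs GWC alone.
# All base values, ranges and distribution families as printed in the
# published model-input table (2021 USD; probabilities per 1-month cycle).
# The interpretation block resolves structurally ambiguous printed rows; this
# variant keeps every printed row literal (no reinterpretation)
#
name: on101-dfu-literal
states: [healed, uDFU, iDFU, gangrene, postamputation, death]
initial_state: uDFU
death_state: death
horizon_cycles: 60
discount_rate_annual: 0.03
wtp_thresholds: [32787, 98361]

settings:
  half_cycle: false

interpretation:
  healed_recurrence: direct
  idfu_self: self-redundant
  postamp_gangrene: direct

transitions:
  - {from: uDFU,           to: healed,         base: 0.259, low: 0.1295, high: 0.3885, dist: beta}
  - {from: uDFU,           to: iDFU,           base: 0.068, low: 0.034,  high: 0.102,  dist: beta}
  - {from: uDFU,           to: death,          base: 0.001, low: 0.0005, high: 0.0015, dist: beta}
  - {from: iDFU,           to: iDFU,           base: 0.084, low: 0.042,  high: 0.126,  dist: beta}
  - {from: iDFU,           to: postamputation, base: 0.016, low: 0.008,  high: 0.024,  dist: beta}
  - {from: iDFU,           to: gangrene,       base: 0.036, low: 0.018,  high: 0.054,  dist: beta}
  - {from: iDFU,           to: death,          base: 0.001, low: 0.0005, high: 0.0015, dist: beta}
  - {from: healed,         to: uDFU,           base: 0.038, low: 0.019,  high: 0.057,  dist: beta}   # "healing to progression"
  - {from: healed,         to: iDFU,           base: 0.211, low: 0.1055, high: 0.3165, dist: beta}
  - {from: healed,         to: death,          base: 0.001, low: 0.0005, high: 0.0015, dist: beta}
  - {from: postamputation, to: iDFU,           base: 0.007, low: 0.0035, high: 0.0105, dist: beta}
  - {from: postamputation, to: gangrene,       base: 0.43,  low: 0.215,  high: 0.645,  dist: beta}
  - {from: postamputation, to: death,          base: 0.003, low: 0.0015, high: 0.0045, dist: beta}
  - {from: gangrene,       to: postamputation, base: 0.313, low: 0.1565, high: 0.4695, dist: beta}
  - {from: gangrene,       to: death,          base: 0.01,  low: 0.005,  high: 0.015,  dist: beta}

utilities:   # per year, uniform distributions
  healed:         {base: 0.84, low: 0.756, high: 0.924, dist: uniform}
  uDFU:           {base: 0.75, low: 0.675, high: 0.825, dist: uniform}
  iDFU:           {base: 0.70, low: 0.63,  high: 0.77,  dist: uniform}
  gangrene:       {base: 0.69, low: 0.621, high: 0.759, dist: uniform}
  postamputation: {base: 0.59, low: 0.531, high: 0.649, dist: uniform}

state_costs:  # per monthly cycle, 2021 USD, triangular distributions
  healed:         {base: 9,   low: 4,   high: 13,  dist: triangular}
  uDFU:           {base: 97,  low: 49,  high: 146, dist: triangular}
  iDFU:           {base: 160, low: 80,  high: 240, dist: triangular}
  gangrene:       {base: 231, low: 116, high: 347, dist: triangular}
  postamputation: {base: 504, low: 252, high: 756, dist: triangular}

initial_event_cost: {name: initial_dfu, base: 161, low: 80, high: 241, dist: triangular}

event_costs:  # one-time hospitalization costs on the listed transitions
  - name: hospitalization_infection
    from: [healed, uDFU, iDFU, gangrene]
    to: iDFU
    base: 8847
    low: 4423
    high: 13270
    dist: triangular
  - name: hospitalization_amputation
    from: [healed, uDFU, iDFU, gangrene]
    to: postamputation
    base: 7552
    low: 3776
    high: 11328
    dist: triangular
  - name: hospitalization_postamputation_infection
    from: [postamputation]
    to: iDFU
    base: 13583
    low: 6791
    high: 20374
    dist: triangular
  - name: hospitalization_postamputation_gangrene
    from: [postamputation]
    to: gangrene
    base: 13583
    low: 6791
    high: 20374
    dist: triangular

drug:
  monthly_cost: {base: 608, low: 304, high: 912, dist: triangular}
  states: [uDFU]        # accrues while an uninfected ulcer is being treated
  cap_cycles: .inf      # uncapped

effect:
  or: {base: 2.30, low: 1.15, high: 3.45, dist: lognormal}
  target: {from: uDFU, to: healed}
  scale: odds           # odds-scale effect, rows exactly as printed

strategies:
  - {label: GWC,         apply_healing_or: false, drug_cost: false}
  - {label: "ON101+GWC", apply_healing_or: true,  drug_cost: true}
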