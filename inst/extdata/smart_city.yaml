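unit: neighborhood
cycle_length: 1 year
horizon: 5
wtp: 700.0
states:
- label: A
  description: extremely high pollution level
  exposure: 40.0
- label: B
  description: slightly high pollution level
  exposure: 30.0
- label: C
  description: medium pollution level
  exposure: 20.0
- label: D
  description: low pollution level
  exposure: 10.0
initial: [0.40, 0.50, 0.09, 0.01]
arms:
  intervention:
    label: intervention
    transition: transition_intervention.csv
    costs:
      single: 500.0
      periodic: 20.0
      indirect: [30.0, 25.0, 20.0, 15.0]
    effects: [0.6, 0.7, 0.8, 0.9]
  comparator:
    label: non-intervention
    transition: transition_comparator.csv
    costs:
      single: 0.0
      periodic: 30.0
      indirect: [30.0, 25.0, 20.0, 15.0]
    effects: [0.6, 0.7, 0.8, 0.9]
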