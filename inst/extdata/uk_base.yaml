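label: uk_base
cohort_size: 100000
iterations: 10
seed: 1
max_age: 100
event_order: screen_last
tables:
  life: uk_life_synthetic.csv
  onset: nl_onset.csv
  progression: nl_progression.csv
regression: 0.0488
clinical: 0.05
screening:
  start_age: 50
  end_age: 71
  interval: 3
  participation: 0.76
  sensitivity: 0.86
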