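# Example pipeline configuration (scaled-down trial for demonstration).
trial:
  n_control: 4000
  n_mms: 2000
  n_uss: 2000
  test_cost: 20
analysis:
  discount_rates: [0.015, 0.035]
  n_bootstrap: 50
  seed: 1
extrapolation:
  horizon: 25
  df_grid: [1, 2, 3]
  test_costs: [15, 30, 40, 50]
markov:
  incidence: 0.0006
  psa_draws: 50
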