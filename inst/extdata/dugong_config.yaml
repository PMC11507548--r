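# declarative specification of the bundled two-study example
original:
  label: Study 1 (linear model, OLS, n=20 biased)
  background: dugong growth; small field sample with recording bias
  pre_data: {variables: [age, weight]}
  model: {family: linear}
  post_data: {family: least_squares}
  data_structure: {sample_size: 20, age_bias: 0.8, weight_bias: 1.2}
replication:
  label: Study 2 (nonlinear model, Bayesian, n=100 clean)
  background: dugong growth; large clean sample
  pre_data: {variables: [age]}
  model: {family: nonlinear}
  post_data: {family: bayesian, burn_in: 1000, samples: 1000}
  data_structure: {sample_size: 100}
result: {type: breeding_status_match, threshold: 2.5}
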