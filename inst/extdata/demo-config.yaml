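# Demo pipeline configuration: a small simulated cohort, whole-sample and
# APOE-stratified composite-risk analyses.
n: 300
seed: 42
analyses: [RQ1, RQ2]
risk_measures: [mcrs]
center_age: 75
exclusions: true
generator:
  prop_female: 0.66
truth:
  beta_risk_on_intercept: -0.161
  beta_risk_on_slope: -0.007
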