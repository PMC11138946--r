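# Example simulation configuration: heterogeneous population, half
# prevalence-only (group -1) and half additionally trend-responsive
# (group +1), strong pro-prophylactic in-group pressure in both.
profiles:
  population: "0xD"   # quoted: bare 0xD would parse as a hex integer
  alpha: [0.1, 0.1]
  m0: 0.05
params:
  beta0: 1
  kappa: 0.9
  pi: 0.5
  tau: 3
init:
  S_m1: 49998
  S_p1: 49998
  E0: 2
  Ia0: 1
  Is0: 1
horizon: 1000
settings:
  rtol: 1.0e-8
  atol: 1.0e-5
  out_step: 0.5
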