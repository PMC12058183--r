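insecticides:
- id: alpha_cyp
  z50: 900.0
  kmax: 1.0
  'n': 1.0
  omega0: 1.0
  delta_b: 0.015
  delta_r: 0.08
  tau_b: 20.0
  decay_exponent: 1.0
- id: pbo_pyr
  z50: 900.0
  kmax: 1.0
  'n': 1.0
  omega0: 1.0
  delta_b: 0.015
  delta_r: 0.08
  tau_b: 20.0
  decay_exponent: 1.0
genetics:
  h2:
    alpha_cyp: 0.2
    pbo_pyr: 0.2
  beta: 15.7
exposure:
  x: 0.7
  m: 0.7
fitness_cost:
  mode: fixed
  female: 0.2
  male: 0.2
sigma:
  mode: fixed
  sigma: 30.0
  phi3: 0.1
  phi4: 20.0
landscape:
  coverage: 0.7
  dispersal: 0.3
alpha:
  alpha_cyp:
    alpha_cyp: 1.0
    pbo_pyr: 0.1
  pbo_pyr:
    alpha_cyp: 0.1
    pbo_pyr: 1.0
cycles:
  d: 1.0
  g: 3.0
  gmax: 5.0
start_prs:
  alpha_cyp: 0.0
  pbo_pyr: 0.0
n_bins: 1001.0
calibration:
  phi1: 0.48
  phi2: 0.15
options:
  mean_survival_mode: at_mean
  dispersal_mode: conserving
  per_cycle_dispersal: no
  beta_scales_costs: no
strategy:
  kind: rotation
  arsenal: ~
  withdrawal: 0.1
  return_threshold: 0.08
  interval: 10.0
  cap: 300.0
  generations_per_year: 10.0
  coverage: ~
  doses: ~
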