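seed: 42
states:
  prior: prior
  reweighted: reweighted
stages:
  simulate: yes
  fit_relaxation: yes
  convert_o2: yes
  orderparams: yes
  reweight: yes
  entropy: yes
simulate:
  wells:
  - 60.0
  - 180.0
  - -60.0
  prior_populations:
  - 0.3333333
  - 0.3333333
  - 0.3333333
  target_populations:
  - 0.6
  - 0.2
  - 0.2
  libration_sd: 10.0
  theta_bond: 109.47
  exchange_prob: 0.2
  n_frames: 2000
  n_residues: 3
  decay:
    eta: 30.0
    delta: 5.0
    amplitude: 1.0
    rates:
    - 40.0
    - 120.0
    fractions:
    - 0.5
    - 0.5
    delays_s:
    - 0.0004
    - 0.002
    - 0.0036
    - 0.0052
    - 0.0068
    - 0.0084
    - 0.01
    noise_sd: 0.02
relaxation:
  n_exp: 2
  chains: 2
  n_draws: 400
  warmup: 600
saxs:
  rg: 37.85
  rg_sd: 0.4
  rg_unit: angstrom
  viscosity_cP: 1.099
  temperature_K: 298.15
  tau_samples: 1000
orderparams:
  max_lag: 200
reweight:
  theta_grid:
  - 0.01
  - 0.0316228
  - 0.1
  - 0.3162278
  - 1.0
  - 3.1622777
  - 10.0
  - 31.6227766
  - 100.0
  - 316.227766
  - 1000.0
  - 3162.2776602
  - 10000.0
  target_sd: 0.02
entropy:
  bin_width: 10.0
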