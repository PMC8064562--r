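# Default synthetic study: mirrors the shape of a 26-site, five-marker
# barcode survey with four underlying species, moderately structured
# populations and a 19-variable environmental landscape.
seed: 42
distance:
  model: K2P
simulate:
  sequences:
    k_species: 4
    n_per: 8
    length: 600
    intra: 0.005
    inter: 0.08
    kappa: 2.0
    markers: [rbcL, matK, trnH-psbA, ITS2, ycf]
  popgen:
    n_pops: 4
    n_per: 6
    migration_mix: 0.3
  hits:
    score_noise_sd: 0.0
    decoy_rate: 0.2
  landscape:
    n_vars: 19
    nrows: 60
    ncols: 60
    dominant_coeff: 5.0
    n_presence: 200
delimit:
  P_min: 0.001
  P_max: 0.100
  n_steps: 10
  X: 1.5
  W: 10
  report_prior: 0.01
assign:
  method: optimized
  deviation: 0.01
popgen:
  n_perm: 1023
sdm:
  test_fraction: 0.25
  beta: 1.0
  background: 10000
  min_flagged_vars: 3
  jackknife: true
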