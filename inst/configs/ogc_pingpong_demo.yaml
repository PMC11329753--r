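# Demonstration pipeline configuration: oxoglutarate-carrier-like homo-exchange
# experiment simulated under a ping-pong rate law, then analysed end-to-end.
seed: 20240627
simulate:
  mechanism: ping_pong
  params:
    vmax: 200      # nmol mg^-1 min^-1
    km_ext: 5      # uM
    km_int: 200    # uM
    ki_ext: 0
  internal_conc_uM: [100, 250, 500, 1000]
  external_conc_uM: [0.5, 1.0, 1.5, 2.5, 5.0, 10, 15, 20]
  time_points_s: [0, 10, 20, 30, 40, 50, 60, 90, 120]
  filtration_delay_s: 0
  background_external_uM: 2.5
  replicates:
    technical: 3
    biological: 2
  noise:
    counting_cv: 0.05
    background_offset: 0.5
    poisson_scale: 0
    biological_cv: 0.10
analysis:
  alpha: 0.05
  weighting: inverse_variance
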