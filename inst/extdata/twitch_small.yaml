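# Example configuration: small quarter-section isometric twitch
geometry:
  segment_length: 1.0
  cross_section: [6.0, 6.0]
  n_myofibrils: 9
  element_size: 0.5
  jsr_spacing: 0.4
  mito_placement_seed: 1
fractions:
  myofibril: 54
  mitochondria: 35
  cytosol: 8
  jsr: 0.03
  nsr: 3
material:
  kappa_S: 25
  K_perm: 700
  restriction: 0.08
protocol:
  mode: isometric_twitch
  duration: 20
  pacing_rate: 1
  output_stride: 200
stepping:
  dt_mech: 1.0
  dt_elec: 0.01
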