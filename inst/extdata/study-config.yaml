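# Study configuration template: the two reference patients and the model
# defaults. Diameters in mm, flows in m^3/s, velocities in m/s, pressures
# in mmHg, lengths in m.
patients:
  patient1:
    d_mpv: 16.45
    d_sv: 8.98
    d_smv: 10.38
    d_lpv: 9.60
    d_rpv: 8.96
    q_mpv_post: 7.86e-5
    p_pv: 25
  patient2:
    d_mpv: 16.27
    d_sv: 14.18
    d_smv: 16.08
    d_lpv: 12.92
    d_rpv: 9.75
    q_mpv_post: 8.73e-5
    p_pv: 25
segment_lengths:
  mpv: 0.040
  lpv: 0.030
  rpv: 0.030
  tee_offset: 0.010
loss_model:
  regime_threshold: 2300
  k_contraction: 0.45
  k_bend: 0.25
wss_thresholds:
  venous_low: 6
  shunt_low: 10
  high: 15
cohort:
  "n": 25    # quoted: a bare n is YAML-1.1 shorthand for false
  seed: 42
  ranges:
    d_mpv: [14, 18]
    d_sv: [8, 15]
    d_smv: [10, 17]
    d_lpv: [9, 13]
    d_rpv: [8, 10]
    v_mpv_pre: [0.1, 0.3]
    p_pv: [20, 30]
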