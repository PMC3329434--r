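# Example rotumble scenario: swimming in homogeneous motility buffer.
# Units: um/s (speeds), s (times), rad^2/s (D_r), Hz (frame_rate).
v_run: 20.0
mean_run: 1.0
tumble_kind: discrete_exponential
tumble_mean: 0.14
tumble_step: 0.1
d_r: 2.1
frame_rate: 10.0
duration: 20.0
n_tracks: 50
chi_run: 0.0
chi_tumble: 0.0
mode: planar
seed: 1
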