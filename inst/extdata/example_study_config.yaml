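n_models: 50.0
seed: 1
cl_list:
- 600.0
- 550.0
- 500.0
- 450.0
- 400.0
- 350.0
n_prebeats:
- 100.0
- 50.0
- 50.0
- 50.0
- 50.0
- 50.0
n_prebeats_confirm:
- 400.0
- 300.0
- 300.0
- 300.0
- 300.0
- 300.0
n_record: 8.0
apd_thresh: 5.0
cat_thresh: 0.05
ranges: ~
ari_params:
  ari_intercept: 113.0
  ari_slope: 0.22
  patient_sd: 18.0
  site_sd: 15.0
  noise_sd: 4.0
  alternans_fraction: 0.1
  alternans_amp_range:
  - 5.0
  - 25.0
  n_beats: 8.0
  activation_latency: 20.0
run_block: yes
run_kinetics: yes
block_fractions:
- 0.2
- 0.4
- 0.6
workers: 1.0
biomarker_cls:
- 600.0
- 350.0
dt_fine: 0.01
dt_coarse: 0.1
fine_win: 30.0
dvdt_thresh: 3.0
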