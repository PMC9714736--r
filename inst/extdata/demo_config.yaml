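output_dir: results/demo_run
stages:
- simulate
- kinematics
- tpc
- fertkin
- factorial
seed: 1
design: {}
factorial_design:
  temperatures:
  - 8.0
  - 16.0
  - 24.0
  phs:
  - 7.1
  - 7.5
  - 7.9
truth: {}
tpc_models:
- quadratic
- gaussian
- modgaussian
n_boot: 150
breadth_threshold: 0.8
motility_threshold: 5.0
kinetics:
  egg_diameter_um: 130.0
  e0_per_ul: 0.02
  t_s: 900.0
  s0_per_ul: 0.4545454545454546
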