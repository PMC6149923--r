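lattice:
  n_per_axis: 100
init:
  n_cells: 100
drugs:
  - name: erlotinib
    half_life_h: 36
    initial_uM: 20
  - name: imatinib
    half_life_h: 18
    initial_uM: 40
phenotype:
  lambda: 1
  c1: 0.025
  c2: 0.06
  theta: [0.1789, 0.0076, 0.0031]
  p_pro: 0.8
time:
  step_h: 0.72
  horizon_steps: 67
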