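# Scaled-down sensitivity study over the four mechanism parameters.
parameters:
  lambda_c:    {lower: 10,      upper: 3000}
  D:           {lower: 1.0e-14, upper: 5.0e-13}
  lambda_A:    {lower: 5,       upper: 300}
  J_cell_cell: {lower: 0,       upper: 120}
fixed:
  n_cells: 25
  A_target: 50
  lattice_size: 96
  n_mcs: 1500
Nq: 4
p_hat_max: 3
replicates: 3
base_seed: 1
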