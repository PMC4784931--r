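id: di-16:0_outward
bilayer:
  acyl_label: di-16:0
  d_l_nm: 2.7
  h_head_nm: 0.8
  K_A_N_per_m: 0.24
  K_B_J: 8.500000000000001e-20
channel:
  state: closed
  d_p_nm: 2.7
  R_ave_nm: 2.5
  pore_outer_radius_nm: 2.5
  pore_constriction_radius_nm: 0.25
  constriction_z_nm: -0.45
  taper_exponent: 2.0
  wall_radius_nm: 3.5
  E_Pa: 40000000.0
  nu: 0.5
  C_P_per_nm: 0.0
  C_P_star_per_nm: 0.0
curvature:
  C1_per_nm: 0.04
  C2_per_nm: 0.04
  theta_rad: 0.0
solver:
  R_out_nm: 20.0
  lambda_nm: 2.0
  h_target_nm: 0.25
rng_seed: 1

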