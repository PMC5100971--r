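dialect: printed
eq8_numerator: I2
kin:
  f1: 1.0
  f2: 10.0
  sigma_M_alpha: 2.4
  sigma_M_gamma: 24.0
  sigma_M10: 24.0
  sigma_M_beta: 24.0
  M0: 0.0015
  mu_M: 1.0
  nu_gamma_M: 8.199999999999999e-06
  nu_gamma_1: 4.1e-05
  nu_4M: 5.83e-05
  nu_42: 0.000175
  nu_6M: 0.00363
  nu_10M: 0.000372
  nu_10r: 0.00112
  nu_12M: 0.000265
  nu_2117: 0.000805
  nu_alpha_M: 0.021
  nu_alpha_1: 0.0735
  nu_beta_M: 5.6e-09
  nu_beta_r: 3.9e-08
  nu_21: 4.1e-05
  n_2r: 3.0
  delta_gamma: 29.120000000000001
  delta_4: 349.370000000000005
  delta_6: 29.109999999999999
  delta_10: 116.480000000000004
  delta_12: 8.33
  delta_21: 63.979999999999997
  delta_alpha: 388.149999999999977
  delta_beta: 349.370000000000005
  delta_2: 537.460000000000036
  mu_1: 1.4
  mu_2: 1.4
  mu_17: 1.4
  mu_r: 1.4
  sigma_12: 10.93
  sigma_2: 1.23
  sigma_4: 1.94
  sigma_21: 156.169999999999987
  sigma_6: 156.169999999999987
  sigma_beta: 14.02
  sigma_10: 14.02
sat:
  zeta_6: 8.0e-06
  zeta_alpha: 9.75e-06
  zeta_10: 1.54e-06
  zeta_2: 6.860000000000001e-08
  zeta_gamma: 2.58e-06
  zeta_12: 4.9e-08
  zeta_4: 9.699999999999999e-09
  zeta_21: 4.25e-06
  zeta_beta: 6.77e-12
  gamma_1: 0.183
  gamma_2: 0.0535
  gamma_r1: 0.0606
  gamma_r2: 0.0606
  gamma_r17: 0.0606
  gamma_17: 0.337
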