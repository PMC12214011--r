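{
  "description": "Reference nondimensional parameter set (printed values)",
  "nondimensional": {
    "delta_u": 100,
    "delta_w": 100,
    "alpha": 0.07,
    "mu_u": 0.167,
    "mu_w": 55.56,
    "rho_u": 0.692,
    "rho_w": 2.5,
    "sigma_u": 0,
    "sigma_w": 0,
    "gamma_v": 0.1,
    "gamma_w": 1e-3
  }
}
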