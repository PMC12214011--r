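{
  "description": "Reference dimensional parameter set (point values; c chosen so alpha = 0.07, diffusivities set for delta_u = delta_w = 100 relative to d_T = 1.21e-6 cm^2/day)",
  "dimensional": {
    "d_E": 1.21e-4,
    "d_T": 1.21e-6,
    "d_IL": 1.21e-4,
    "c": 0.02268,
    "m_E": 0.03,
    "m_IL": 10,
    "p_E": 0.1245,
    "p_T": 0.1,
    "p_IL": 5,
    "g_E": 2e7,
    "g_T": 1e5,
    "g_IL": 1e3,
    "s_E": 0,
    "s_IL": 0,
    "r_T": 0.18,
    "b": 1e-6
  }
}
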