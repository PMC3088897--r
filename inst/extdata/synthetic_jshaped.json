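{
  "label": "synthetic jshaped",
  "type": "fractional_polynomial",
  "link": "log",
  "powers": [0.5, 1],
  "betas": [-0.15, 0.022],
  "beta_cov": [0.0004, -3e-05, -3e-05, 9e-06],
  "rr_former": 1.1
}
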