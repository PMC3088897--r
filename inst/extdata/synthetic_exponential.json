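{
  "label": "synthetic exponential",
  "type": "fractional_polynomial",
  "link": "log",
  "powers": 1,
  "betas": 0.01,
  "beta_cov": 2.25e-06,
  "rr_former": 1.2
}
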