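{
  "label": "synthetic linear",
  "type": "fractional_polynomial",
  "link": "identity",
  "powers": 1,
  "betas": 0.012,
  "beta_cov": 4e-06,
  "rr_former": 1
}
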