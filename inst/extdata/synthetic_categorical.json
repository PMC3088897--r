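{
  "label": "synthetic categorical",
  "type": "categorical",
  "band_bounds": [0, 0.25, 20, 40, 150],
  "rrs": [1, 0.95, 1.1, 1.4],
  "rr_former": 1.1
}
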