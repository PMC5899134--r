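{
  "a_plus_M": 0.0001,
  "a_minus_M": 200,
  "b0_M": 1,
  "R_total": 2500,
  "monitor": {
    "name": "monitor",
    "rbs_strength": 1,
    "mrna_conc": 900,
    "length_bp": 720,
    "gamma": 1
  }
}
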