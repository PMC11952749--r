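{
  "r_in": 4,
  "t_in": 4,
  "r_out": 0.7,
  "t_out": 3
}
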