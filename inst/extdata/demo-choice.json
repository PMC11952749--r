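{
  "r_in": 2.5,
  "t_in": 2.5,
  "r_out": 2.4,
  "t_out": 6,
  "choice": {
    "ss": {"reward": 2.5, "duration": 2.5},
    "ll": {"reward": 5, "duration": 8.5}
  }
}
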