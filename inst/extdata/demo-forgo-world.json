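{
  "pursuits": [
    {"label": "rich", "reward": 2, "duration": 1, "frequency": 0.5},
    {"label": "lean", "reward": 4, "duration": 2, "frequency": 0.25}
  ],
  "default_rate": 0
}
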