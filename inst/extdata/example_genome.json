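{
  "genome": {
    "name": "human5",
    "chromosomes": [
      {"length_M": 0.75, "count": 2},
      {"length_M": 1.25, "count": 8},
      {"length_M": 1.75, "count": 6},
      {"length_M": 2.10, "count": 4},
      {"length_M": 2.75, "count": 2}
    ]
  }
}
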