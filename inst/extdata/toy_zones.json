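{
  "zones": {
    "none": [[0, 0], [15, 0], [60, 45], [60, 60], [45, 60], [0, 15]],
    "mild": [
      [[15, 0], [60, 0], [60, 45]],
      [[0, 15], [45, 60], [0, 60]]
    ]
  },
  "domain": [0, 60]
}
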