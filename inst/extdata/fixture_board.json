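{
  "condition": "custom_4_pair",
  "n_pairs": 4,
  "seed": "NA",
  "apertures": [
    [0, 0],
    [0, 1],
    [0, 2],
    [0, 3],
    [0, 4],
    [1, 0],
    [1, 1],
    [1, 2]
  ],
  "sounds": ["bee", "lion", "frog", "bee", "rooster", "lion", "frog", "rooster"]
}
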