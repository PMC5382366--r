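{
  "step": [0, 1, 2, 3, 4],
  "n_attractors": [16, 8, 4, 2, 1],
  "top5_mean_basin": [0.0625, 0.125, 0.25, 0.5, 1],
  "score": [0, 0, 0, 0, 0]
}
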