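{
  "node": ["P", "Q"],
  "activity_baseline": [1, 1],
  "activity_perturbed": [0.5, 0.5]
}
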