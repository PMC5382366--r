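{
  "id": ["0|3", "1", "2"],
  "period": [2, 1, 1],
  "basin_count": [2, 1, 1]
}
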