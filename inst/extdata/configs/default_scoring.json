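{
  "aspects": ["proliferation", "EMT", "stemness"],
  "rules": {
    "proliferation": [
      {"marker": "CyclinE", "desired": 0, "weight": 1},
      {"marker": "CyclinD", "desired": 0, "weight": 1},
      {"marker": "p21", "desired": 1, "weight": 1}
    ],
    "EMT": [
      {"marker": "Snail", "desired": 0, "weight": 1},
      {"marker": "SLUG", "desired": 0, "weight": 1},
      {"marker": "MMP", "desired": 0, "weight": 1},
      {"marker": "Ecadherin", "desired": 1, "weight": 1}
    ],
    "stemness": [
      {"marker": "Snail", "desired": 0, "weight": 1}
    ]
  },
  "aspect_weights": [6, 4, 1]
}
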