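{
  "nodes": [
    {"name": "EGF", "role": "input"},
    {"name": "Wnt", "role": "input"},
    {"name": "DNAdamage", "role": "input"},
    {"name": "KRAS", "role": "internal"},
    {"name": "APC", "role": "internal"},
    {"name": "p53", "role": "internal"},
    {"name": "Snail", "role": "marker"},
    {"name": "SLUG", "role": "marker"},
    {"name": "MMP", "role": "marker"},
    {"name": "Ecadherin", "role": "marker"},
    {"name": "CyclinE", "role": "marker"},
    {"name": "CyclinD", "role": "marker"},
    {"name": "p21", "role": "marker"},
    {"name": "Caspase3", "role": "marker"}
  ],
  "edges": [
    {"source": "Snail", "target": "Caspase3", "weight": -1},
    {"source": "p53", "target": "Caspase3", "weight": 2},
    {"source": "KRAS", "target": "CyclinD", "weight": 2},
    {"source": "p21", "target": "CyclinD", "weight": -1},
    {"source": "CyclinD", "target": "CyclinE", "weight": 2},
    {"source": "p21", "target": "CyclinE", "weight": -1},
    {"source": "Snail", "target": "Ecadherin", "weight": -2},
    {"source": "EGF", "target": "KRAS", "weight": 2},
    {"source": "Snail", "target": "MMP", "weight": 2},
    {"source": "Snail", "target": "SLUG", "weight": 2},
    {"source": "APC", "target": "Snail", "weight": -1},
    {"source": "KRAS", "target": "Snail", "weight": 1},
    {"source": "Wnt", "target": "Snail", "weight": 2},
    {"source": "DNAdamage", "target": "p53", "weight": 2},
    {"source": "p53", "target": "p21", "weight": 2}
  ],
  "basal": {
    "normal": [0, 0, 0, -1, 1, -1, -1, -1, -1, 1, -1, -1, -1, -1],
    "disease": [0, 0, 0, 1, -1, -2, -1, -1, -1, 1, -1, -1, -1, -1]
  }
}
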