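{
  "schema": "dynpath-graph/1",
  "nodes": [
    {"name": "X", "role": "treatment"},
    {"name": "Y", "role": "outcome"},
    {"name": "L", "role": "mediator"},
    {"name": "C", "role": "censoring"}
  ],
  "edges": [
    {"from": "X", "to": "Y"},
    {"from": "X", "to": "C"},
    {"from": "X", "to": "L"},
    {"from": "L", "to": "Y"}
  ]
}
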