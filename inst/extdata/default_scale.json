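{
  "terms": [
    {"label": "VH", "tfn": [0.75, 1, 1]},
    {"label": "H", "tfn": [0.5, 0.75, 1]},
    {"label": "M", "tfn": [0.25, 0.5, 0.75]},
    {"label": "L", "tfn": [0, 0.25, 0.5]},
    {"label": "VL", "tfn": [0, 0, 0.25]}
  ]
}
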