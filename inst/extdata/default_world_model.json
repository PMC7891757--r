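{
  "units": "cm",
  "regions": [
    {"id": 1, "label": "ATT", "rect": [8, 9, 14, 21]},
    {"id": 2, "label": "SPD", "rect": [5, 9, 8, 21]},
    {"id": 3, "label": "VS", "rect": [14, 9, 17, 21]},
    {"id": 4, "label": "FMA", "rect": [6, 21, 16, 24]},
    {"id": 5, "label": "HDG", "rect": [6, 5, 16, 8]},
    {"id": 6, "label": "ND", "rect": [22, 5, 38, 18]},
    {"id": 7, "label": "NDz", "rect": [30, 18, 38, 24]},
    {"id": 8, "label": "FCU", "rect": [20, 25, 40, 30]},
    {"id": 9, "label": "ECAM", "rect": [40, 5, 56, 24]},
    {"id": 10, "label": "OTW", "rect": [0, 30, 60, 50]}
  ]
}
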