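{
  "instrument": "sus",
  "seed": 1,
  "groups": [
    { "label": "under15", "n": 7, "mean": 73.93, "sd": 4.97 },
    { "label": "over16", "n": 9, "mean": 82.5, "sd": 4.68 }
  ]
}
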