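[
  {
    "metabolite_id": "l_fucose",
    "source": "HMDB00174",
    "shifts_h": [
      {"assignment": "CH3b", "ppm": 1.26},
      {"assignment": "CH3a", "ppm": 1.20},
      {"assignment": "H5b", "ppm": 3.80},
      {"assignment": "H5a", "ppm": 4.18},
      {"assignment": "H1a", "ppm": 5.19},
      {"assignment": "H1b", "ppm": 4.54},
      {"assignment": "H2b", "ppm": 3.46}
    ],
    "shifts_c": [
      {"assignment": "CH3b", "ppm": 18.3},
      {"assignment": "CH3a", "ppm": 18.3},
      {"assignment": "H1a", "ppm": 95.1},
      {"assignment": "H1b", "ppm": 99.0}
    ],
    "couplings": [
      {"assignment1": "CH3b", "assignment2": "H5b", "hz": 6.5},
      {"assignment1": "CH3a", "assignment2": "H5a", "hz": 6.7},
      {"assignment1": "H1a", "assignment2": "H2a", "hz": 3.9},
      {"assignment1": "H1b", "assignment2": "H2b", "hz": 7.9}
    ]
  }
]
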