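[
  {
    "metabolite_id": "l_fucose",
    "provenance": "curated",
    "shifts": [
      {"ppm": 1.25, "assignment": "CH3b"},
      {"ppm": 1.22, "assignment": "CH3a"},
      {"ppm": 3.80, "assignment": "H5b"},
      {"ppm": 4.20, "assignment": "H5a"},
      {"ppm": 5.22, "assignment": "H1a"},
      {"ppm": 4.57, "assignment": "H1b"},
      {"ppm": 3.46, "assignment": "H2b"}
    ],
    "multiplicities": [
      {"assignment": "CH3b", "label": "d"},
      {"assignment": "CH3a", "label": "d"},
      {"assignment": "H1a", "label": "d"},
      {"assignment": "H1b", "label": "d"}
    ],
    "couplings": [
      {"assignment1": "CH3b", "assignment2": "H5b", "hz": 6.5},
      {"assignment1": "CH3a", "assignment2": "H5a", "hz": 6.6},
      {"assignment1": "H1a", "assignment2": "H2a", "hz": 4.0},
      {"assignment1": "H1b", "assignment2": "H2b", "hz": 7.8}
    ],
    "cosy": [
      {"assignment1": "CH3b", "assignment2": "H5b"},
      {"assignment1": "CH3a", "assignment2": "H5a"},
      {"assignment1": "H1a", "assignment2": "H2a"},
      {"assignment1": "H1b", "assignment2": "H2b"},
      {"assignment1": "H2b", "assignment2": "H3b"}
    ],
    "hsqc": [
      {"ppm_h": 1.25, "ppm_c": 18.47, "assignment": "CH3b"},
      {"ppm_h": 1.22, "ppm_c": 18.4, "assignment": "CH3a"},
      {"ppm_h": 5.22, "ppm_c": 95.5, "assignment": "H1a"},
      {"ppm_h": 4.57, "ppm_c": 99.5, "assignment": "H1b"}
    ],
    "hmbc": [
      {"ppm_c": 73.7, "assignment": "CH3b"}
    ],
    "second_order": 0
  },
  {
    "metabolite_id": "ketoleucine",
    "provenance": "curated",
    "shifts": [
      {"ppm": 0.941, "assignment": "CH3"},
      {"ppm": 2.098, "assignment": "CH"},
      {"ppm": 2.618, "assignment": "CH2"}
    ],
    "multiplicities": [
      {"assignment": "CH3", "label": "d"},
      {"assignment": "CH", "label": "t sept"},
      {"assignment": "CH2", "label": "d"}
    ],
    "couplings": [
      {"assignment1": "CH3", "assignment2": "CH", "hz": 6.6},
      {"assignment1": "CH", "assignment2": "CH2", "hz": 7.0}
    ],
    "cosy": [
      {"assignment1": "CH3", "assignment2": "CH"},
      {"assignment1": "CH", "assignment2": "CH2"}
    ],
    "hsqc": [
      {"ppm_h": 0.941, "ppm_c": 24.5, "assignment": "CH3"}
    ],
    "second_order": 0
  },
  {
    "metabolite_id": "hiba_2",
    "provenance": "curated",
    "shifts": [{"ppm": 1.36, "assignment": "CH3"}],
    "multiplicities": [{"assignment": "CH3", "label": "s"}],
    "hsqc": [{"ppm_h": 1.36, "ppm_c": 27.2, "assignment": "CH3"}],
    "second_order": 0
  },
  {
    "metabolite_id": "succinic_acid",
    "provenance": "curated",
    "shifts": [{"ppm": 2.41, "assignment": "CH2"}],
    "multiplicities": [{"assignment": "CH2", "label": "s"}],
    "hsqc": [{"ppm_h": 2.41, "ppm_c": 36.9, "assignment": "CH2"}],
    "hmbc": [{"ppm_c": 183.3, "assignment": "CH2"}],
    "second_order": 0
  },
  {
    "metabolite_id": "tartaric_acid",
    "provenance": "curated",
    "shifts": [{"ppm": 4.34, "assignment": "CH"}],
    "multiplicities": [{"assignment": "CH", "label": "s"}],
    "hsqc": [{"ppm_h": 4.34, "ppm_c": 76.0, "assignment": "CH"}],
    "hmbc": [{"ppm_c": 179.5, "assignment": "CH"}],
    "second_order": 0
  },
  {
    "metabolite_id": "allantoin",
    "provenance": "curated",
    "shifts": [{"ppm": 5.39, "assignment": "CH"}],
    "multiplicities": [{"assignment": "CH", "label": "s"}],
    "hsqc": [{"ppm_h": 5.39, "ppm_c": 65.6, "assignment": "CH"}],
    "hmbc": [{"ppm_c": 160.5, "assignment": "CH"}],
    "second_order": 0
  },
  {
    "metabolite_id": "guanidoacetic_acid",
    "provenance": "curated",
    "shifts": [{"ppm": 3.80, "assignment": "CH2"}],
    "multiplicities": [{"assignment": "CH2", "label": "s"}],
    "hsqc": [{"ppm_h": 3.80, "ppm_c": 47.5, "assignment": "CH2"}],
    "hmbc": [{"ppm_c": 158.5, "assignment": "CH2"}],
    "second_order": 0
  },
  {
    "metabolite_id": "phenylacetic_acid",
    "provenance": "curated",
    "shifts": [{"ppm": 3.54, "assignment": "CH2"}],
    "multiplicities": [{"assignment": "CH2", "label": "s"}],
    "hsqc": [
      {"ppm_h": 3.54, "ppm_c": 45.3, "assignment": "CH2"},
      {"ppm_h": 7.30, "ppm_c": 131.9, "assignment": "Hortho"},
      {"ppm_h": 7.37, "ppm_c": 131.2, "assignment": "Hmeta"},
      {"ppm_h": 7.29, "ppm_c": 129.5, "assignment": "Hpara"}
    ],
    "hmbc": [
      {"ppm_c": 181.0, "assignment": "CH2"},
      {"ppm_c": 138.2, "assignment": "CH2"},
      {"ppm_c": 131.9, "assignment": "CH2"}
    ],
    "evidence": [
      {"kind": "long_range_cosy",
       "description": "4-bond COSY between methylene and ortho aromatic protons"}
    ],
    "second_order": 1
  },
  {
    "metabolite_id": "methylsuccinic_acid",
    "provenance": "curated",
    "shifts": [{"ppm": 1.08, "assignment": "CH3"}],
    "multiplicities": [{"assignment": "CH3", "label": "d"}],
    "couplings": [{"assignment1": "CH3", "assignment2": "CH", "hz": 7.2}],
    "cosy": [{"assignment1": "CH3", "assignment2": "CH"}],
    "second_order": 0
  },
  {
    "metabolite_id": "trans_aconitic_acid",
    "provenance": "curated",
    "shifts": [
      {"ppm": 6.59, "assignment": "Holefin"},
      {"ppm": 3.45, "assignment": "CH2"}
    ],
    "multiplicities": [
      {"assignment": "Holefin", "label": "s"},
      {"assignment": "CH2", "label": "s"}
    ],
    "hsqc": [{"ppm_h": 6.59, "ppm_c": 134.0, "assignment": "Holefin"}],
    "evidence": [
      {"kind": "long_range_cosy",
       "description": "4-bond COSY between olefin and methylene protons"},
      {"kind": "long_range_coupling",
       "description": "0.8 Hz fine coupling on olefin and methylene signals",
       "hz": 0.8}
    ],
    "second_order": 0
  },
  {
    "metabolite_id": "choline",
    "provenance": "curated",
    "shifts": [{"ppm": 3.19, "assignment": "NMe3"}],
    "multiplicities": [{"assignment": "NMe3", "label": "s"}],
    "hsqc": [{"ppm_h": 3.19, "ppm_c": 56.6, "assignment": "NMe3"}],
    "hmbc": [
      {"ppm_c": 56.6, "assignment": "NMe3"},
      {"ppm_c": 68.2, "assignment": "NMe3"}
    ],
    "evidence": [
      {"kind": "heteronuclear_coupling",
       "description": "2J(14N,1H) 1:1:1 triplet on the methyl signal",
       "hz": 0.6}
    ],
    "second_order": 0
  },
  {
    "metabolite_id": "l_carnitine",
    "provenance": "curated",
    "shifts": [{"ppm": 3.21, "assignment": "NMe3"}],
    "multiplicities": [{"assignment": "NMe3", "label": "s"}],
    "hsqc": [{"ppm_h": 3.21, "ppm_c": 54.8, "assignment": "NMe3"}],
    "hmbc": [
      {"ppm_c": 54.8, "assignment": "NMe3"},
      {"ppm_c": 70.9, "assignment": "NMe3"}
    ],
    "second_order": 0
  },
  {
    "metabolite_id": "dimethylglycine",
    "provenance": "curated",
    "shifts": [{"ppm": 2.93, "assignment": "NMe2"}],
    "multiplicities": [{"assignment": "NMe2", "label": "s"}],
    "hsqc": [{"ppm_h": 2.93, "ppm_c": 46.8, "assignment": "NMe2"}],
    "hmbc": [
      {"ppm_c": 46.8, "assignment": "NMe2"},
      {"ppm_c": 62.1, "assignment": "NMe2"}
    ],
    "second_order": 0
  },
  {
    "metabolite_id": "betaine",
    "provenance": "curated",
    "shifts": [{"ppm": 3.27, "assignment": "NMe3"}],
    "multiplicities": [{"assignment": "NMe3", "label": "s"}],
    "hsqc": [{"ppm_h": 3.27, "ppm_c": 55.9, "assignment": "NMe3"}],
    "hmbc": [
      {"ppm_c": 55.9, "assignment": "NMe3"},
      {"ppm_c": 69.0, "assignment": "NMe3"}
    ],
    "second_order": 0
  },
  {
    "metabolite_id": "n_propionylglycine",
    "provenance": "curated",
    "shifts": [{"ppm": 1.14, "assignment": "CH3"}],
    "multiplicities": [{"assignment": "CH3", "label": "t"}],
    "couplings": [{"assignment1": "CH3", "assignment2": "CH2p", "hz": 7.6}],
    "cosy": [{"assignment1": "CH3", "assignment2": "CH2p"}],
    "second_order": 0
  }
]
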