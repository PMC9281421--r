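{
  "schema_version": 2,
  "states": [
    {
      "label": "T(pipi*1)",
      "fragment": "T",
      "character": "LE_pipi",
      "symmetry": "A'",
      "oscillator_strength": 0.20399999999999999
    },
    {
      "label": "T(nOpi*1)",
      "fragment": "T",
      "character": "LE_npi",
      "symmetry": "A''",
      "oscillator_strength": 0.0
    },
    {
      "label": "A(La)",
      "fragment": "A",
      "character": "LE_pipi",
      "symmetry": "A'",
      "oscillator_strength": 0.126
    },
    {
      "label": "A(Lb)",
      "fragment": "A",
      "character": "LE_pipi",
      "symmetry": "A'",
      "oscillator_strength": 0.20300000000000001
    },
    {
      "label": "A(nNpi*1)",
      "fragment": "A",
      "character": "LE_npi",
      "symmetry": "A''",
      "oscillator_strength": 0.0
    },
    {
      "label": "A->T(CT)",
      "fragment": "A->T",
      "character": "CT",
      "symmetry": "A'",
      "oscillator_strength": 0.0030000000000000001
    },
    {
      "label": "A(nNpi*2)",
      "fragment": "A",
      "character": "LE_npi",
      "symmetry": "A''",
      "oscillator_strength": 0.0
    },
    {
      "label": "T(nOpi*2)",
      "fragment": "T",
      "character": "LE_npi",
      "symmetry": "A''",
      "oscillator_strength": 0.0
    },
    {
      "label": "A(nNpi*3)",
      "fragment": "A",
      "character": "LE_npi",
      "symmetry": "A''",
      "oscillator_strength": 0.0030000000000000001
    },
    {
      "label": "T(pipi*2)",
      "fragment": "T",
      "character": "LE_pipi",
      "symmetry": "A'",
      "oscillator_strength": 0.017000000000000001
    },
    {
      "label": "T(pipi*3)",
      "fragment": "T",
      "character": "LE_pipi",
      "symmetry": "A'",
      "oscillator_strength": 0.29599999999999999
    },
    {
      "label": "A(pipi*3)",
      "fragment": "A",
      "character": "LE_pipi",
      "symmetry": "A'",
      "oscillator_strength": 0.26800000000000002
    }
  ],
  "modes": {
    "frequencies": [],
    "labels": null,
    "symmetry": null
  },
  "constant_matrix": [
    [5.3499999999999996, 0.0, 0.0, 0.0, 0.0, 0.0, 0.0, 0.0, 0.0, 0.0, 0.0, 0.0],
    [0.0, 5.4199999999999999, 0.0, 0.0, 0.0, 0.0, 0.0, 0.0, 0.0, 0.0, 0.0, 0.0],
    [0.0, 0.0, 5.4800000000000004, 0.0, 0.0, 0.0, 0.0, 0.0, 0.0, 0.0, 0.0, 0.0],
    [0.0, 0.0, 0.0, 5.5800000000000001, 0.0, 0.0, 0.0, 0.0, 0.0, 0.0, 0.0, 0.0],
    [0.0, 0.0, 0.0, 0.0, 5.7599999999999998, 0.0, 0.0, 0.0, 0.0, 0.0, 0.0, 0.0],
    [0.0, 0.0, 0.0, 0.0, 0.0, 6.1600000000000001, 0.0, 0.0, 0.0, 0.0, 0.0, 0.0],
    [0.0, 0.0, 0.0, 0.0, 0.0, 0.0, 6.2000000000000002, 0.0, 0.0, 0.0, 0.0, 0.0],
    [0.0, 0.0, 0.0, 0.0, 0.0, 0.0, 0.0, 6.4500000000000002, 0.0, 0.0, 0.0, 0.0],
    [0.0, 0.0, 0.0, 0.0, 0.0, 0.0, 0.0, 0.0, 6.5899999999999999, 0.0, 0.0, 0.0],
    [0.0, 0.0, 0.0, 0.0, 0.0, 0.0, 0.0, 0.0, 0.0, 6.6600000000000001, 0.0, 0.0],
    [0.0, 0.0, 0.0, 0.0, 0.0, 0.0, 0.0, 0.0, 0.0, 0.0, 6.7400000000000002, 0.0],
    [0.0, 0.0, 0.0, 0.0, 0.0, 0.0, 0.0, 0.0, 0.0, 0.0, 0.0, 6.7599999999999998]
  ],
  "couplings": [
    [
      [],
      [],
      [],
      [],
      [],
      [],
      [],
      [],
      [],
      [],
      [],
      []
    ],
    [
      [],
      [],
      [],
      [],
      [],
      [],
      [],
      [],
      [],
      [],
      [],
      []
    ],
    [
      [],
      [],
      [],
      [],
      [],
      [],
      [],
      [],
      [],
      [],
      [],
      []
    ],
    [
      [],
      [],
      [],
      [],
      [],
      [],
      [],
      [],
      [],
      [],
      [],
      []
    ],
    [
      [],
      [],
      [],
      [],
      [],
      [],
      [],
      [],
      [],
      [],
      [],
      []
    ],
    [
      [],
      [],
      [],
      [],
      [],
      [],
      [],
      [],
      [],
      [],
      [],
      []
    ],
    [
      [],
      [],
      [],
      [],
      [],
      [],
      [],
      [],
      [],
      [],
      [],
      []
    ],
    [
      [],
      [],
      [],
      [],
      [],
      [],
      [],
      [],
      [],
      [],
      [],
      []
    ],
    [
      [],
      [],
      [],
      [],
      [],
      [],
      [],
      [],
      [],
      [],
      [],
      []
    ],
    [
      [],
      [],
      [],
      [],
      [],
      [],
      [],
      [],
      [],
      [],
      [],
      []
    ],
    [
      [],
      [],
      [],
      [],
      [],
      [],
      [],
      [],
      [],
      [],
      [],
      []
    ],
    [
      [],
      [],
      [],
      [],
      [],
      [],
      [],
      [],
      [],
      [],
      [],
      []
    ]
  ]
}
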