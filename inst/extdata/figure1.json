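{
  "format": "ducg-model",
  "version": 1,
  "variables": [
    {
      "id": "B1",
      "n_states": 2
    },
    {
      "id": "B2",
      "n_states": 3
    },
    {
      "id": "X3",
      "n_states": 2
    },
    {
      "id": "X4",
      "n_states": 2
    },
    {
      "id": "X5",
      "n_states": 2
    },
    {
      "id": "X6",
      "n_states": 3
    },
    {
      "id": "X7",
      "n_states": 3
    },
    {
      "id": "X8",
      "n_states": 2
    },
    {
      "id": "X9",
      "n_states": 2
    },
    {
      "id": "X10",
      "n_states": 3
    },
    {
      "id": "D10",
      "n_states": 1
    },
    {
      "id": "X11",
      "n_states": 3
    },
    {
      "id": "G12",
      "n_states": 2
    }
  ],
  "arcs": [
    {
      "parent": "X7",
      "child": "X3",
      "r": 1,
      "a": [
        [
          null,
          null,
          null
        ],
        [
          null,
          0,
          0.5
        ]
      ]
    },
    {
      "parent": "X8",
      "child": "X4",
      "r": 1,
      "a": [
        [
          null,
          null
        ],
        [
          null,
          0.6
        ]
      ]
    },
    {
      "parent": "B2",
      "child": "X5",
      "r": 1,
      "a": [
        [
          null,
          null,
          null
        ],
        [
          null,
          0.2,
          0
        ]
      ]
    },
    {
      "parent": "X4",
      "child": "X5",
      "r": 1,
      "a": [
        [
          null,
          null
        ],
        [
          null,
          0.8
        ]
      ]
    },
    {
      "parent": "X8",
      "child": "X6",
      "r": 1,
      "a": [
        [
          null,
          null
        ],
        [
          null,
          0.6
        ],
        [
          null,
          0
        ]
      ]
    },
    {
      "parent": "X8",
      "child": "X7",
      "r": 1,
      "a": [
        [
          null,
          null
        ],
        [
          null,
          0
        ],
        [
          null,
          0.9
        ]
      ]
    },
    {
      "parent": "B1",
      "child": "X8",
      "r": 1,
      "a": [
        [
          null,
          null
        ],
        [
          null,
          0.9
        ]
      ]
    },
    {
      "parent": "B2",
      "child": "X8",
      "r": 1,
      "a": [
        [
          null,
          null,
          null
        ],
        [
          null,
          0.6,
          0
        ]
      ]
    },
    {
      "parent": "X6",
      "child": "X9",
      "r": 1,
      "a": [
        [
          null,
          null,
          null
        ],
        [
          null,
          0.6,
          0
        ]
      ]
    },
    {
      "parent": "D10",
      "child": "X10",
      "r": 1,
      "a": [
        [
          null
        ],
        [
          0.2
        ],
        [
          0.8
        ]
      ]
    },
    {
      "parent": "G12",
      "child": "X11",
      "r": 1,
      "a": [
        [
          null,
          null
        ],
        [
          null,
          0
        ],
        [
          null,
          0.9
        ]
      ]
    }
  ],
  "gates": [
    {
      "gate": "G12",
      "inputs": [
        "X9",
        "X10"
      ],
      "state_exprs": {
        "1": [
          [
            {
              "var": "X9",
              "state": 1
            },
            {
              "var": "X10",
              "state": 2
            }
          ],
          [
            {
              "var": "X10",
              "state": 1
            }
          ]
        ]
      }
    }
  ],
  "priors": [
    {
      "variable": "B1",
      "b": [
        null,
        0.02
      ]
    },
    {
      "variable": "B2",
      "b": [
        null,
        0.02,
        0.04
      ]
    }
  ],
  "categories": {
    "exclusive": [],
    "concurrent": []
  }
}
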