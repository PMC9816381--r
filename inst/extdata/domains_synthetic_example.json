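[
  {
    "subunit": "GluN1",
    "domain": "ATD1",
    "ranges": [
      [
        1,
        10
      ]
    ]
  },
  {
    "subunit": "GluN1",
    "domain": "ATD2",
    "ranges": [
      [
        11,
        20
      ]
    ]
  },
  {
    "subunit": "GluN1",
    "domain": "LBD",
    "ranges": [
      [
        21,
        30
      ],
      [
        41,
        50
      ]
    ]
  },
  {
    "subunit": "GluN1",
    "domain": "TMD",
    "ranges": [
      [
        31,
        40
      ],
      [
        51,
        60
      ]
    ]
  },
  {
    "subunit": "GluN2A",
    "domain": "ATD1",
    "ranges": [
      [
        4,
        13
      ]
    ]
  },
  {
    "subunit": "GluN2A",
    "domain": "ATD2",
    "ranges": [
      [
        14,
        23
      ]
    ]
  },
  {
    "subunit": "GluN2A",
    "domain": "LBD",
    "ranges": [
      [
        24,
        33
      ],
      [
        44,
        53
      ]
    ]
  },
  {
    "subunit": "GluN2A",
    "domain": "TMD",
    "ranges": [
      [
        34,
        43
      ],
      [
        54,
        63
      ]
    ]
  },
  {
    "subunit": "GluN2B",
    "domain": "ATD1",
    "ranges": [
      [
        6,
        15
      ]
    ]
  },
  {
    "subunit": "GluN2B",
    "domain": "ATD2",
    "ranges": [
      [
        16,
        25
      ]
    ]
  },
  {
    "subunit": "GluN2B",
    "domain": "LBD",
    "ranges": [
      [
        26,
        35
      ],
      [
        46,
        55
      ]
    ]
  },
  {
    "subunit": "GluN2B",
    "domain": "TMD",
    "ranges": [
      [
        36,
        45
      ],
      [
        56,
        65
      ]
    ]
  }
]
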