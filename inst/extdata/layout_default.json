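{
  "n_rows": 8,
  "n_cols": 12,
  "origin": [60, 60],
  "pitch": [40, 40],
  "roi": {
    "shape": "disk",
    "size": 10
  },
  "wells": [
    {
      "well": "A1",
      "sensor": "DC1",
      "condition": 1,
      "role": "control",
      "pair": "DC1c1"
    },
    {
      "well": "A2",
      "sensor": "DC1",
      "condition": 1,
      "role": "analyte",
      "pair": "DC1c1"
    },
    {
      "well": "A3",
      "sensor": "DC1",
      "condition": 2,
      "role": "control",
      "pair": "DC1c2"
    },
    {
      "well": "A4",
      "sensor": "DC1",
      "condition": 2,
      "role": "analyte",
      "pair": "DC1c2"
    },
    {
      "well": "B1",
      "sensor": "DC2",
      "condition": 1,
      "role": "control",
      "pair": "DC2c1"
    },
    {
      "well": "B2",
      "sensor": "DC2",
      "condition": 1,
      "role": "analyte",
      "pair": "DC2c1"
    },
    {
      "well": "B3",
      "sensor": "DC2",
      "condition": 2,
      "role": "control",
      "pair": "DC2c2"
    },
    {
      "well": "B4",
      "sensor": "DC2",
      "condition": 2,
      "role": "analyte",
      "pair": "DC2c2"
    },
    {
      "well": "C1",
      "sensor": "DC3",
      "condition": 1,
      "role": "control",
      "pair": "DC3c1"
    },
    {
      "well": "C2",
      "sensor": "DC3",
      "condition": 1,
      "role": "analyte",
      "pair": "DC3c1"
    },
    {
      "well": "C3",
      "sensor": "DC3",
      "condition": 2,
      "role": "control",
      "pair": "DC3c2"
    },
    {
      "well": "C4",
      "sensor": "DC3",
      "condition": 2,
      "role": "analyte",
      "pair": "DC3c2"
    },
    {
      "well": "D1",
      "sensor": "DC4",
      "condition": 1,
      "role": "control",
      "pair": "DC4c1"
    },
    {
      "well": "D2",
      "sensor": "DC4",
      "condition": 1,
      "role": "analyte",
      "pair": "DC4c1"
    },
    {
      "well": "D3",
      "sensor": "DC4",
      "condition": 2,
      "role": "control",
      "pair": "DC4c2"
    },
    {
      "well": "D4",
      "sensor": "DC4",
      "condition": 2,
      "role": "analyte",
      "pair": "DC4c2"
    },
    {
      "well": "E1",
      "sensor": "DC5",
      "condition": 1,
      "role": "control",
      "pair": "DC5c1"
    },
    {
      "well": "E2",
      "sensor": "DC5",
      "condition": 1,
      "role": "analyte",
      "pair": "DC5c1"
    },
    {
      "well": "E3",
      "sensor": "DC5",
      "condition": 2,
      "role": "control",
      "pair": "DC5c2"
    },
    {
      "well": "E4",
      "sensor": "DC5",
      "condition": 2,
      "role": "analyte",
      "pair": "DC5c2"
    },
    {
      "well": "F1",
      "sensor": "DC6",
      "condition": 1,
      "role": "control",
      "pair": "DC6c1"
    },
    {
      "well": "F2",
      "sensor": "DC6",
      "condition": 1,
      "role": "analyte",
      "pair": "DC6c1"
    },
    {
      "well": "F3",
      "sensor": "DC6",
      "condition": 2,
      "role": "control",
      "pair": "DC6c2"
    },
    {
      "well": "F4",
      "sensor": "DC6",
      "condition": 2,
      "role": "analyte",
      "pair": "DC6c2"
    },
    {
      "well": "G1",
      "sensor": "DC7",
      "condition": 1,
      "role": "control",
      "pair": "DC7c1"
    },
    {
      "well": "G2",
      "sensor": "DC7",
      "condition": 1,
      "role": "analyte",
      "pair": "DC7c1"
    },
    {
      "well": "G3",
      "sensor": "DC7",
      "condition": 2,
      "role": "control",
      "pair": "DC7c2"
    },
    {
      "well": "G4",
      "sensor": "DC7",
      "condition": 2,
      "role": "analyte",
      "pair": "DC7c2"
    },
    {
      "well": "H1",
      "sensor": "DC8",
      "condition": 1,
      "role": "control",
      "pair": "DC8c1"
    },
    {
      "well": "H2",
      "sensor": "DC8",
      "condition": 1,
      "role": "analyte",
      "pair": "DC8c1"
    },
    {
      "well": "H3",
      "sensor": "DC8",
      "condition": 2,
      "role": "control",
      "pair": "DC8c2"
    },
    {
      "well": "H4",
      "sensor": "DC8",
      "condition": 2,
      "role": "analyte",
      "pair": "DC8c2"
    }
  ]
}
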