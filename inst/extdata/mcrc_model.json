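{
  "schema": "mavt-model/1",
  "name": "mCRC second-line biologics (post-workshop)",
  "tree": {
    "root": "overall value",
    "clusters": [
      {
        "id": "therapeutic",
        "name": "Therapeutic impact",
        "attributes": [
          "os",
          "hrqol",
          "pfs"
        ]
      },
      {
        "id": "safety",
        "name": "Safety profile",
        "attributes": [
          "g4ae"
        ]
      },
      {
        "id": "innovation",
        "name": "Innovation level",
        "attributes": [
          "atc_l4",
          "phase3",
          "mkt_auth",
          "posology"
        ]
      },
      {
        "id": "socioeconomic",
        "name": "Socioeconomic impact",
        "attributes": [
          "medical_costs"
        ]
      }
    ]
  },
  "attributes": [
    {
      "id": "os",
      "name": "Overall survival",
      "cluster": "therapeutic",
      "metric": "median time from randomisation to death",
      "units": "months",
      "scale": "continuous",
      "direction": "increasing",
      "range": [6.2, 14.9],
      "lower_ref": 6.2,
      "higher_ref": 14.9
    },
    {
      "id": "hrqol",
      "name": "HRQoL",
      "cluster": "therapeutic",
      "metric": "health-related quality of life, EQ-5D utility",
      "units": "utility",
      "scale": "continuous",
      "direction": "increasing",
      "range": [0.75, 0.9],
      "lower_ref": 0.75,
      "higher_ref": 0.9
    },
    {
      "id": "pfs",
      "name": "Progression free survival",
      "cluster": "therapeutic",
      "metric": "median survival without disease progression",
      "units": "months",
      "scale": "continuous",
      "direction": "increasing",
      "range": [1.9, 7.6],
      "lower_ref": 1.9,
      "higher_ref": 7.6
    },
    {
      "id": "g4ae",
      "name": "Grade 4 AEs",
      "cluster": "safety",
      "metric": "patients experiencing a Grade 4 adverse event",
      "units": "% of patients",
      "scale": "continuous",
      "direction": "decreasing",
      "range": [0, 21],
      "lower_ref": 10,
      "higher_ref": 0
    },
    {
      "id": "atc_l4",
      "name": "ATC L4",
      "cluster": "innovation",
      "metric": "relative market entrance in the ATC chemical class",
      "units": "",
      "scale": "binary",
      "direction": "increasing",
      "levels": [
        "2nd or later",
        "1st"
      ],
      "lower_ref": "2nd or later",
      "higher_ref": "1st"
    },
    {
      "id": "phase3",
      "name": "Phase 3",
      "cluster": "innovation",
      "metric": "new indications investigated in Phase 3 trials",
      "units": "indications",
      "scale": "continuous",
      "direction": "increasing",
      "range": [0, 21],
      "lower_ref": 0,
      "higher_ref": 21
    },
    {
      "id": "mkt_auth",
      "name": "Marketing authorisation",
      "cluster": "innovation",
      "metric": "new indications with marketing authorisation",
      "units": "indications",
      "scale": "continuous",
      "direction": "increasing",
      "range": [0, 3],
      "lower_ref": 0,
      "higher_ref": 3
    },
    {
      "id": "posology",
      "name": "Posology",
      "cluster": "innovation",
      "metric": "administration duration and dose frequency",
      "units": "",
      "scale": "ordinal",
      "direction": "increasing",
      "levels": [
        "Many hours, every 2 weeks",
        "1 hour, every week",
        "Up to 1 hour, every 2 weeks"
      ],
      "lower_ref": "Many hours, every 2 weeks",
      "higher_ref": "Up to 1 hour, every 2 weeks"
    },
    {
      "id": "medical_costs",
      "name": "Medical costs impact",
      "cluster": "socioeconomic",
      "metric": "impact on direct medical costs excluding drug purchase",
      "units": "GBP",
      "scale": "continuous",
      "direction": "decreasing",
      "range": [0, 7086],
      "lower_ref": 7086,
      "higher_ref": 0
    }
  ],
  "value_functions": [
    {
      "attribute": "os",
      "type": "piecewise_linear",
      "anchors": [
        [6.2, 0],
        [10, 44.4],
        [10.4, 48.9],
        [13.5, 83.9],
        [14.9, 100]
      ]
    },
    {
      "attribute": "hrqol",
      "type": "piecewise_linear",
      "anchors": [
        [0.75, 0],
        [0.78, 15],
        [0.9, 100]
      ]
    },
    {
      "attribute": "pfs",
      "type": "piecewise_linear",
      "anchors": [
        [1.9, 0],
        [4.1, 51.4],
        [4.4, 55.6],
        [6.9, 90.3],
        [7.6, 100]
      ]
    },
    {
      "attribute": "g4ae",
      "type": "piecewise_linear",
      "anchors": [
        [0, 100],
        [5, 50],
        [7, 30],
        [10, 0],
        [21, -117.9]
      ]
    },
    {
      "attribute": "atc_l4",
      "type": "level_lookup",
      "scores": {
        "2nd or later": 0,
        "1st": 100
      }
    },
    {
      "attribute": "phase3",
      "type": "piecewise_linear",
      "anchors": [
        [0, 0],
        [7, 19.4],
        [18, 50],
        [19, 66.7],
        [21, 100]
      ]
    },
    {
      "attribute": "mkt_auth",
      "type": "piecewise_linear",
      "anchors": [
        [0, 0],
        [1, 30],
        [3, 100]
      ]
    },
    {
      "attribute": "posology",
      "type": "level_lookup",
      "scores": {
        "Many hours, every 2 weeks": 0,
        "1 hour, every week": 37.5,
        "Up to 1 hour, every 2 weeks": 100
      }
    },
    {
      "attribute": "medical_costs",
      "type": "piecewise_linear",
      "anchors": [
        [0, 100],
        [1940, 78.9],
        [4589, 50],
        [6738, 7],
        [7086, 0]
      ]
    }
  ],
  "weights": {
    "precise": {
      "os": 28.9,
      "hrqol": 12.8,
      "pfs": 4.8,
      "g4ae": 23.3,
      "atc_l4": 5.8,
      "phase3": 2.3,
      "mkt_auth": 3.5,
      "posology": 7,
      "medical_costs": 11.6
    },
    "printed": {
      "os": 29,
      "hrqol": 13,
      "pfs": 5,
      "g4ae": 23,
      "atc_l4": 6,
      "phase3": 2,
      "mkt_auth": 3,
      "posology": 7,
      "medical_costs": 12
    }
  }
}
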