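{
  "schema": "mavt-model/1",
  "name": "mCRC pre-workshop model (documentation)",
  "tree": {
    "root": "overall value",
    "clusters": [
      {
        "id": "therapeutic",
        "name": "Therapeutic impact",
        "attributes": [
          "os",
          "hrqol",
          "pfs",
          "orr"
        ]
      },
      {
        "id": "safety",
        "name": "Safety profile",
        "attributes": [
          "g3ae",
          "g4ae",
          "contraindications"
        ]
      },
      {
        "id": "innovation",
        "name": "Innovation level",
        "attributes": [
          "atc_l1",
          "atc_l2",
          "atc_l3",
          "atc_l4",
          "atc_l5",
          "phase1",
          "phase2",
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
      "metric": "",
      "units": "months",
      "scale": "continuous",
      "direction": "increasing",
      "range": [0, 14.9],
      "lower_ref": 0,
      "higher_ref": 6.2
    },
    {
      "id": "hrqol",
      "name": "HRQoL",
      "cluster": "therapeutic",
      "metric": "",
      "units": "utility",
      "scale": "continuous",
      "direction": "increasing",
      "range": [0.6, 0.9],
      "lower_ref": 0.6,
      "higher_ref": 0.75
    },
    {
      "id": "pfs",
      "name": "Progression free survival",
      "cluster": "therapeutic",
      "metric": "",
      "units": "months",
      "scale": "continuous",
      "direction": "increasing",
      "range": [0, 7.6],
      "lower_ref": 0,
      "higher_ref": 1.9
    },
    {
      "id": "orr",
      "name": "Objective response rate",
      "cluster": "therapeutic",
      "metric": "",
      "units": "% of patients",
      "scale": "continuous",
      "direction": "increasing",
      "range": [0, 100],
      "lower_ref": 0,
      "higher_ref": 11
    },
    {
      "id": "g3ae",
      "name": "Grade 3 AEs",
      "cluster": "safety",
      "metric": "",
      "units": "% of patients",
      "scale": "continuous",
      "direction": "decreasing",
      "range": [0, 68],
      "lower_ref": 68,
      "higher_ref": 32
    },
    {
      "id": "g4ae",
      "name": "Grade 4 AEs",
      "cluster": "safety",
      "metric": "",
      "units": "% of patients",
      "scale": "continuous",
      "direction": "decreasing",
      "range": [0, 24],
      "lower_ref": 24,
      "higher_ref": 10
    },
    {
      "id": "contraindications",
      "name": "Contra-indications",
      "cluster": "safety",
      "metric": "",
      "units": "",
      "scale": "binary",
      "direction": "increasing",
      "levels": [
        "lower expected benefit and higher expected risk",
        "lower expected benefit"
      ],
      "lower_ref": "lower expected benefit and higher expected risk",
      "higher_ref": "lower expected benefit"
    },
    {
      "id": "atc_l1",
      "name": "ATC L1",
      "cluster": "innovation",
      "metric": "",
      "units": "",
      "scale": "ordinal",
      "direction": "increasing",
      "levels": [
        "5th",
        "4th",
        "3rd",
        "2nd",
        "1st"
      ],
      "lower_ref": "5th",
      "higher_ref": "4th"
    },
    {
      "id": "atc_l2",
      "name": "ATC L2",
      "cluster": "innovation",
      "metric": "",
      "units": "",
      "scale": "ordinal",
      "direction": "increasing",
      "levels": [
        "5th",
        "4th",
        "3rd",
        "2nd",
        "1st"
      ],
      "lower_ref": "5th",
      "higher_ref": "4th"
    },
    {
      "id": "atc_l3",
      "name": "ATC L3",
      "cluster": "innovation",
      "metric": "",
      "units": "",
      "scale": "ordinal",
      "direction": "increasing",
      "levels": [
        "5th",
        "4th",
        "3rd",
        "2nd",
        "1st"
      ],
      "lower_ref": "5th",
      "higher_ref": "3rd"
    },
    {
      "id": "atc_l4",
      "name": "ATC L4",
      "cluster": "innovation",
      "metric": "",
      "units": "",
      "scale": "ordinal",
      "direction": "increasing",
      "levels": [
        "5th",
        "4th",
        "3rd",
        "2nd",
        "1st"
      ],
      "lower_ref": "5th",
      "higher_ref": "1st"
    },
    {
      "id": "atc_l5",
      "name": "ATC L5",
      "cluster": "innovation",
      "metric": "",
      "units": "",
      "scale": "ordinal",
      "direction": "increasing",
      "levels": [
        "5th",
        "4th",
        "3rd",
        "2nd",
        "1st"
      ],
      "lower_ref": "5th",
      "higher_ref": "1st"
    },
    {
      "id": "phase1",
      "name": "Phase 1",
      "cluster": "innovation",
      "metric": "",
      "units": "indications",
      "scale": "continuous",
      "direction": "increasing",
      "range": [0, 17],
      "lower_ref": 0,
      "higher_ref": 17
    },
    {
      "id": "phase2",
      "name": "Phase 2",
      "cluster": "innovation",
      "metric": "",
      "units": "indications",
      "scale": "continuous",
      "direction": "increasing",
      "range": [0, 55],
      "lower_ref": 0,
      "higher_ref": 55
    },
    {
      "id": "phase3",
      "name": "Phase 3",
      "cluster": "innovation",
      "metric": "",
      "units": "indications",
      "scale": "continuous",
      "direction": "increasing",
      "range": [0, 18],
      "lower_ref": 0,
      "higher_ref": 18
    },
    {
      "id": "mkt_auth",
      "name": "Marketing authorisation",
      "cluster": "innovation",
      "metric": "",
      "units": "indications",
      "scale": "continuous",
      "direction": "increasing",
      "range": [0, 2],
      "lower_ref": 0,
      "higher_ref": 2
    },
    {
      "id": "posology",
      "name": "Posology",
      "cluster": "innovation",
      "metric": "",
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
      "metric": "",
      "units": "GBP",
      "scale": "continuous",
      "direction": "decreasing",
      "range": [0, 7086],
      "lower_ref": 7086,
      "higher_ref": 4589
    }
  ],
  "value_functions": [],
  "weights": []
}
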