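{
  "id": "min_coupled",
  "metabolites": [
    {
      "id": "A"
    },
    {
      "id": "B"
    }
  ],
  "reactions": [
    {
      "id": "EX_A",
      "metabolites": {
        "A": -1
      },
      "lower_bound": -10,
      "upper_bound": 0,
      "objective_coefficient": 0
    },
    {
      "id": "EX_B",
      "metabolites": {
        "B": -1
      },
      "lower_bound": -10,
      "upper_bound": 0,
      "objective_coefficient": 0
    },
    {
      "id": "GROWTH",
      "metabolites": {
        "A": -1,
        "B": -1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "objective_coefficient": 1
    }
  ]
}
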