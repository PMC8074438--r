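{
  "id": "linear_chain_2",
  "metabolites": [
    {
      "id": "N1"
    },
    {
      "id": "N2"
    }
  ],
  "reactions": [
    {
      "id": "EX_N1",
      "metabolites": {
        "N1": -1
      },
      "lower_bound": -10,
      "upper_bound": 0,
      "objective_coefficient": 0
    },
    {
      "id": "EX_N2",
      "metabolites": {
        "N2": -1
      },
      "lower_bound": -10,
      "upper_bound": 0,
      "objective_coefficient": 0
    },
    {
      "id": "GROW_N1",
      "metabolites": {
        "N1": -1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "objective_coefficient": 1
    },
    {
      "id": "GROW_N2",
      "metabolites": {
        "N2": -1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "objective_coefficient": 2
    }
  ]
}
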