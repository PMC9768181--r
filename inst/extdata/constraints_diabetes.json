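{
  "outcome": "diabetes",
  "family": "binomial",
  "treatment": "activity",
  "intercept": true,
  "variables": [
    {
      "name": "activity",
      "kind": "ordinal",
      "levels": ["1", "2", "3", "4"],
      "reference": "1"
    },
    {
      "name": "age",
      "kind": "continuous-discretized",
      "bin_edges": [18, 35, 50, 65, 120],
      "reference": "1"
    },
    {
      "name": "bmi",
      "kind": "continuous-discretized",
      "bin_edges": [10, 22.5, 25, 30, 60],
      "reference": "1"
    },
    {
      "name": "age_band",
      "kind": "continuous-linear"
    },
    {
      "name": "gender",
      "kind": "binary",
      "reference": "0"
    },
    {
      "name": "smoking",
      "kind": "binary",
      "reference": "0"
    },
    {
      "name": "secondhand",
      "kind": "binary",
      "reference": "0"
    },
    {
      "name": "alcohol",
      "kind": "ordinal",
      "levels": ["1", "2", "3", "4"]
    },
    {
      "name": "trust",
      "kind": "ordinal",
      "levels": ["1", "2", "3", "4"]
    },
    {
      "name": "region",
      "kind": "categorical",
      "levels": ["1", "2", "3", "4", "5"]
    },
    {
      "name": "income",
      "kind": "continuous-linear"
    },
    {
      "name": "education",
      "kind": "continuous-linear"
    }
  ],
  "terms": [
    {
      "variables": "activity",
      "monotonicity": "decreasing",
      "sign": "negative"
    },
    {
      "variables": "age",
      "monotonicity": "increasing",
      "sign": "positive"
    },
    {
      "variables": "bmi",
      "monotonicity": "increasing",
      "sign": "positive"
    },
    {
      "variables": "gender",
      "monotonicity": "none",
      "sign": "positive"
    },
    {
      "variables": "smoking",
      "monotonicity": "none",
      "sign": "positive"
    },
    {
      "variables": "secondhand",
      "monotonicity": "none",
      "sign": "positive"
    },
    {
      "variables": ["age_band", "activity"],
      "monotonicity": "decreasing",
      "sign": "negative"
    },
    {
      "variables": ["smoking", "activity"],
      "monotonicity": "decreasing",
      "sign": "negative"
    },
    {
      "variables": "alcohol",
      "monotonicity": "none",
      "sign": "unrestricted"
    },
    {
      "variables": "trust",
      "monotonicity": "none",
      "sign": "unrestricted"
    },
    {
      "variables": "region",
      "monotonicity": "none",
      "sign": "unrestricted"
    },
    {
      "variables": "income",
      "monotonicity": "none",
      "sign": "unrestricted"
    },
    {
      "variables": "education",
      "monotonicity": "none",
      "sign": "unrestricted"
    }
  ]
}
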