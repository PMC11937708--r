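{
  "name": "synthetic-qlqc30-to-eq5d3l-v1",
  "comment": "Synthetic multinomial-logit response-mapping coefficients with the same structure as published QLQ-C30 to EQ-5D-3L mapping algorithms: per EQ-5D dimension, linear predictors for levels 2 and 3 (level 1 = reference, eta = 0) over selected QLQ-C30 dimension scores on the 0-100 scale. Signs follow clinical direction (better functioning lowers, worse symptoms raise, the odds of EQ-5D dysfunction). For testing and simulation only; substitute published coefficients for real analyses.",
  "dimensions": {
    "mobility": {
      "2": { "(Intercept)": 1.5, "pf": -0.06 },
      "3": { "(Intercept)": -1.0, "pf": -0.09 }
    },
    "self_care": {
      "2": { "(Intercept)": 0.2, "pf": -0.05 },
      "3": { "(Intercept)": -2.0, "pf": -0.06 }
    },
    "usual_activities": {
      "2": { "(Intercept)": 1.8, "rf": -0.05, "fa": 0.01 },
      "3": { "(Intercept)": -0.8, "rf": -0.05, "fa": 0.015 }
    },
    "pain_discomfort": {
      "2": { "(Intercept)": -2.0, "pa": 0.06 },
      "3": { "(Intercept)": -4.5, "pa": 0.065 }
    },
    "anxiety_depression": {
      "2": { "(Intercept)": 3.2, "ef": -0.05 },
      "3": { "(Intercept)": 0.0, "ef": -0.06 }
    }
  }
}
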