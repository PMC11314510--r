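{
  "version": "1.0",
  "note": "Published minimum-adequate-model parameters: logit-scale coefficients, z-scaling constants for continuous predictors, and classification cutoffs.",
  "MAM1": {
    "intercept": -0.79,
    "coefficients": {
      "plant_sex": 0.54,
      "sporophyte_presence": -1.18,
      "substrate_breadth": -0.83
    },
    "scaling": {
      "substrate_breadth": {"mean": 1.69, "sd": 0.94}
    },
    "cutoff": 0.21
  },
  "MAM2": {
    "intercept": -1.65,
    "coefficients": {
      "seta_length": -0.61,
      "substrate_breadth": -0.9
    },
    "scaling": {
      "seta_length": {"mean": 14, "sd": 13.32},
      "substrate_breadth": {"mean": 1.8, "sd": 0.98}
    },
    "cutoff": 0.18
  }
}
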