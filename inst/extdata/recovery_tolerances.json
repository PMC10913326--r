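{
  "rule": "3x pilot median absolute error, rounded up to 3 decimals",
  "pilot_seed": 101,
  "rl": {
    "design": "12 groups x 5 agents x 100 trials, shared parameters",
    "truth": {
      "alpha": 0.3,
      "beta": 0.18,
      "sigma": 0.3,
      "theta": 1.5
    },
    "pilot_mae": {
      "alpha": 0.0449256646647212,
      "beta": 0.0246905522730102,
      "sigma": 0.0307146114700445,
      "theta": 0.255057257786288
    },
    "tolerance": {
      "alpha": 0.135,
      "beta": 0.075,
      "sigma": 0.093,
      "theta": 0.766
    }
  },
  "ddm": {
    "design": "4 datasets x 80 group trials x 5 agents, shared delta_p/s",
    "truth": {
      "delta_p": 0.3,
      "s": 0.2
    },
    "pilot_mae": {
      "delta_p": 0.02649979091194,
      "s": 0.0128170511636267
    },
    "tolerance": {
      "delta_p": 0.08,
      "s": 0.039
    }
  }
}
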