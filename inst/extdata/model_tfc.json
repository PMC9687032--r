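{
  "response": "TFC",
  "units": "mg CAE/g",
  "coding": {
    "factor_names": ["ethanol", "time", "temperature", "power"],
    "centres": [50, 3, 130, 450],
    "steps": [20, 1, 20, 150]
  },
  "beta0": 13.26,
  "beta_linear": [-0.4032, 1.677, -0.6597, 1.51],
  "beta_quad": [0.1636, -0.4717, -1.15, 0.0652],
  "beta_inter": [-0.5511, 1.01, 0.1127, 1.11, 1.8, 0.6715]
}
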