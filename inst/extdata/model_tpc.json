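{
  "response": "TPC",
  "units": "mg GAE/g",
  "coding": {
    "factor_names": ["ethanol", "time", "temperature", "power"],
    "centres": [50, 3, 130, 450],
    "steps": [20, 1, 20, 150]
  },
  "beta0": 35.48,
  "beta_linear": [-0.98, 0.199, -1.19, 1.99],
  "beta_quad": [-2.42, -2.58, -3.33, -1.13],
  "beta_inter": [0.1952, 1.06, 0.7562, 1.41, 1.94, 0.4797]
}
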