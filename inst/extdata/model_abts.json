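{
  "response": "ABTS",
  "units": "% inhibition",
  "coding": {
    "factor_names": ["ethanol", "time", "temperature", "power"],
    "centres": [50, 3, 130, 450],
    "steps": [20, 1, 20, 150]
  },
  "beta0": 41.84,
  "beta_linear": [0.9626, 0.4558, -2.4, 3.13],
  "beta_quad": [-1.47, -1.72, -3.6, -1.54],
  "beta_inter": [-0.6606, 1.44, 0.4581, 1.08, 1.34, -0.4356]
}
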