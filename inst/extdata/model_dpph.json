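{
  "response": "DPPH",
  "units": "% inhibition",
  "coding": {
    "factor_names": ["ethanol", "time", "temperature", "power"],
    "centres": [50, 3, 130, 450],
    "steps": [20, 1, 20, 150]
  },
  "beta0": 26.34,
  "beta_linear": [0.6782, 1.72, -3.42, 1.245],
  "beta_quad": [0.6328, -1.07, -3.42, 0.2118],
  "beta_inter": [-2.99, 0.274, 2.45, 0.1471, -1.02, -1.43]
}
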