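{
  "schema": "crimedyn-config/1",
  "model": "5d",
  "params": {
    "beta": 1, "delta1": 0.3, "sigma1": 0.4, "rho": 1,
    "nu_p": 0.2, "nu_c": 0, "delta2": 0.2, "sigma2": 0.5,
    "phi": 0.3, "eps": 0, "N": 120
  },
  "horizon": 10000,
  "seed": 1
}
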