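{
  "schema": "crimedyn-config/1",
  "model": "9d",
  "params": {
    "beta": 2, "delta1": 0.5, "sigma1": 0.5, "rho1": 1,
    "nu_p1": 0.2, "nu_c1": 0, "phi1": 0.3,
    "delta2": 0.2, "sigma2": 0.5, "rho2": 1,
    "nu_p2": 0.2, "nu_c2": 0, "phi2": 0.3,
    "delta3": 0.2, "sigma3": 0.5, "rho3": 0,
    "eps": 0, "N": 120
  },
  "horizon": 100000,
  "seed": 1
}
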