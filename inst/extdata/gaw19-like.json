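{
  "family_sizes": [65, 55, 45, 62, 49],
  "n_probes": 2000,
  "modules": [
    {
      "size": 150,
      "loading": 0.8,
      "shared": true
    },
    {
      "size": 120,
      "loading": 0.8,
      "shared": true
    },
    {
      "size": 100,
      "loading": 0.8,
      "shared": true
    },
    {
      "size": 90,
      "loading": 0.8,
      "shared": true
    },
    {
      "size": 80,
      "loading": 0.8,
      "shared": false
    },
    {
      "size": 60,
      "loading": 0.8,
      "shared": false
    }
  ],
  "sigma2_g": 1,
  "sigma2_v": 0.5,
  "sigma2_e": 1,
  "n_causal": 15,
  "causal_effect": 0.3,
  "trait_sigma2_g": 1,
  "trait_sigma2_v": 0.5,
  "trait_sigma2_e": 1,
  "age_range": [20, 80],
  "age_effect": 0.02,
  "sex_effect": 0.5,
  "seed": 1
}
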