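{
  "plp": {
    "hbond":  { "V1": 2.3, "V2": 2.6, "V3": 3.1, "V4": 3.6, "V5": 20.0, "V6": -2.5 },
    "steric": { "V1": 3.3, "V2": 3.6, "V3": 4.5, "V4": 6.0, "V5": 20.0, "V6": -0.4 },
    "es_cutoff": 12.0,
    "epsilon": 1e-6
  }
}
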