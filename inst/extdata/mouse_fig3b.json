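{
  "events": [
    {
      "drug": "anti-PD-1",
      "day": 13,
      "gamma": 1e-10
    },
    {
      "drug": "anti-TNF-alpha",
      "day": 13,
      "gamma": 1e-06
    },
    {
      "drug": "anti-PD-1",
      "day": 16,
      "gamma": 1e-10
    },
    {
      "drug": "anti-TNF-alpha",
      "day": 16,
      "gamma": 1e-06
    },
    {
      "drug": "anti-PD-1",
      "day": 19,
      "gamma": 1e-10
    },
    {
      "drug": "anti-TNF-alpha",
      "day": 19,
      "gamma": 1e-06
    }
  ],
  "beta": 1.55,
  "t_end": 30
}
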