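{
  "name": "moderate risk differentials",
  "risks": [0.05, 0.02, 0.01, 0.005],
  "fractions": [0.25, 0.25, 0.25, 0.25]
}
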