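{
  "name": "large risk differentials",
  "risks": [0.1, 0.05, 0.02, 0.01, 0.005, 0.002, 0.001],
  "fractions": [0.142857142857142857, 0.142857142857142857, 0.142857142857142857,
                0.142857142857142857, 0.142857142857142857, 0.142857142857142857,
                0.142857142857142857]
}
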