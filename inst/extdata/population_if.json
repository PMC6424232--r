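{
  "exponential_terms": [
    [200.0, 4.0],
    [35.0, 0.25],
    [10.0, 0.011]
  ],
  "residual_window_min": [55, 85],
  "grid_step_min": 0.1
}
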