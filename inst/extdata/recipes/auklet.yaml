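# Small-alcid (Cassin's auklet style) regime: 3-s sampling, shallow
# (<30 m), brief (<1 min) and frequent dives; level shifts and
# short-term drifts but no missing data, noise under 1 m. A 3-sample
# (9 s) median, then a 0.05 quantile over 180 samples (9 min); the wide
# second window is the compromise that lets the filter adapt to level
# shifts when no missing gaps separate the levels. Window widths are in
# SAMPLES at 3-s sampling.
k: [3, 180]
probs: [0.5, 0.05]
sampling_interval: 3
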