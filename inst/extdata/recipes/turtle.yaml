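# Leatherback-turtle regime: 1-s sampling, high-resolution transducer,
# subtle warm-surface artifacts pulling readings below about -0.4 m.
# Narrow 3-sample (3 s) median smoothing, then a near-minimum 0.05
# quantile over 120 samples (2 min), bounded to the band where the
# surface sits. Window widths are in SAMPLES at 1-s sampling.
k: [3, 120]
probs: [0.5, 0.05]
bounds: [-0.25, 0.75]
sampling_interval: 1
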