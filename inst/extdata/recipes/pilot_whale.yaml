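# Short-finned pilot-whale regime: 1-s sampling, 1-m resolution, fast
# deep dives with brief surface intervals; thermal hysteresis causes
# short-term drifts and level shifts that blend into >3 m surface noise.
# Three steps: a 7-sample (7 s) median, a 0.1 quantile over 7 samples,
# then a 0.01 near-minimum quantile over 30 samples (30 s), bounded to
# 0-10 m. A single wide second window cannot follow the hysteresis, so
# smoothing is split across two narrow steps before the final
# surface-tracking filter. Window widths are in SAMPLES at 1-s sampling.
k: [7, 7, 30]
probs: [0.5, 0.1, 0.01]
bounds: [0, 10]
sampling_interval: 1
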