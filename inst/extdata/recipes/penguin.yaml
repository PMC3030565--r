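# King-penguin regime: 1-s sampling, coarse 0.5-m resolution, deep
# diurnal diving, highly unstable transducer with warm-surface readings
# below -2 m and the surface wandering between -2 and 4 m. An 11-sample
# (11 s) median, then a 0.3 quantile over 120 samples (2 min) — large
# enough to smooth the residual noise, small enough to still find the
# surface — bounded to the band the surface fluctuates in. Window widths
# are in SAMPLES at 1-s sampling.
k: [11, 120]
probs: [0.5, 0.3]
bounds: [-2, 5]
sampling_interval: 1
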