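# Two flat levels separated by a run of missing samples: the canonical
# level-shift fixture.
step_series <- function(n1, gap, n2, low = 0, high = 3) {
  c(rep(low, n1), rep(NA_real_, gap), rep(high, n2))
}

# Minimal regular record; numeric times are seconds since the epoch.
tiny_record <- function(depth, interval = 5) {
  tdr_record(seq(0, by = interval, length.out = length(depth)), depth)
}

# Small-scale analogue of the benchmark corruption for fast tests:
# n = 12000, drift over the first "trip", shift over the second, with a
# gap hiding the transition.
small_experiment <- function(sim_seed, noise_seed, sigma = 1) {
  clean <- simulate_dives(n_samples = 12000, seed = sim_seed)
  ops <- list(op_gap(7000, 8000), op_noise(sigma),
              op_drift(2000, 7000, -2), op_shift(7000, 12000, 3))
  list(clean = corrupt_tdr(clean, list(op_gap(7000, 8000))),
       corrupted = corrupt_tdr(clean, ops, seed = noise_seed))
}
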