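---
title: "Zero-offset correction of dive depth by recursive moving-quantile filtering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Zero-offset correction of dive depth by recursive moving-quantile filtering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(divezoc)
```

## The problem

Time-depth recorders (TDRs) carried by diving animals sample hydrostatic
pressure at a fixed interval. The pressure transducer's zero reading is
not stable: temperature and other factors make it *drift* slowly,
*shift* abruptly between record segments, and wobble with short-term
thermal hysteresis. As a result, readings taken while the animal floats
at the sea surface — which should be exactly 0 m — wander over the
deployment, and every dive depth inherits that error. Zero-offset
correction (ZOC) estimates the wandering surface level and subtracts it.

Diving animals return to the surface constantly, so the record itself
carries the calibration signal: the lower envelope of the depth series,
wherever the animal is at the surface, traces the transducer offset.
The method implemented here extracts that envelope with a chain of
center-aligned running quantiles.

## The method

Let $d_t$ be the recorded depth (metres, positive downwards) at sample
$t$. Given a sequence of window widths $k_1, \dots, k_s$ (in samples)
and quantile fractions $p_1, \dots, p_s \in [0, 1]$, the filter computes

$$f^{(1)} = Q_{k_1, p_1}(d), \qquad f^{(j)} = Q_{k_j, p_j}(f^{(j-1)}),$$

where $Q_{k,p}(x)_t$ is the $p$-quantile of the non-missing values of
$x$ in the window of $k$ samples centred at $t$. The last output
$f^{(s)}$ is the surface-level estimate, and the corrected depth is
$d - f^{(s)}$. Two steps usually suffice: a narrow running median
($p = 0.5$) to suppress noise without eroding brief surface intervals,
then a wide low quantile to ride the lower envelope through drifts and
level shifts. Regimes with thermal hysteresis may need three steps
(see the shipped `pilot_whale` recipe) because no single wide window can
follow fast short-term drift.

Optionally the process is *bounded*: with `depth_bounds = c(lower, upper)`
each step only filters the samples of its input that lie inside the
band where the surface can plausibly be, and fills the positions outside
it by linear interpolation between the nearest in-band outputs, so every
step's output keeps full length. Bounding prevents bouts of frequent
deep diving from dragging the quantile away from the surface. Membership
in the band is re-evaluated on each step's own input: step 1 masks on
the raw depth, step 2 on step 1's output, and so on — each step is
self-contained, and the choice is isolated in one place in the code so
it could be flipped to a fixed raw-depth mask if a use case demanded it.

### Window semantics, precisely

These conventions are pinned down because results — especially small
quantiles on small windows — depend on them:

* **Centre alignment.** The window at sample $i$ covers
  $i - \lfloor (k-1)/2 \rfloor \dots i + \lfloor k/2 \rfloor$: even
  widths take the extra sample on the right.
* **Ends.** At the series ends the window is clipped to the available
  samples and the quantile is taken over what remains. The alternative
  (emit missing at the ends) was rejected because the correction must
  cover the whole record.
* **Missing data.** The window never narrows: the quantile is computed
  over the $k - m$ observations present when $m$ of the window's
  samples are missing, and is itself missing when $m = k$. With
  `na_rm = TRUE` missing samples are instead deleted before filtering,
  the compacted series is filtered, outputs are reinserted at the
  original positions, and missing positions stay missing — appropriate
  (and faster) only when the gaps hide no change in surface trend.
* **Quantile definition.** Linear interpolation between order
  statistics (`stats::quantile()` type 7).

The engine maintains a sorted window updated incrementally at both
edges (compiled code), and is verified element-for-element against a
per-window collect–drop–sort–interpolate oracle
(`brute_force_quantile()`) over randomized instances in the test suite.
A million samples at $k = 720$ filter in well under a second.

### Window width, gaps and level shifts

How wide may the second window be? The danger is a window that spans a
level shift: observations from the old level then pollute the quantile.
A run of missing samples separating the levels protects the estimate,
and the test suite characterises the relationship empirically on
two-level step fixtures (a low level, a gap of $g$ missing samples, a
high level), sweeping $k$, $g$ and $p$:

* For the **median** ($p = 0.5$) the window width is irrelevant: the
  local level always holds a strict majority in any window centred on
  an observation, so the median reproduces both levels exactly — for
  any $k$ and any gap, even $g = 0$ adjacent to the boundary
  (ties at an exactly balanced window are the only caveat, and they
  cannot arise with the center-aligned cover above).
* For **small quantiles** ($p$ near 0) the estimate adjacent to the gap
  is exact whenever $k \le 2g$: with the cover above, no window centred
  on an observation then reaches across the gap at all. Once
  $k \ge 2g + 3$ the window centred on the first sample of the upper
  level sees lower-level observations and a near-minimum quantile
  follows the wrong level. Hence the practical rule: *do not choose the
  window wider than twice the missing run separating the levels* when
  using small quantiles.

Level shifts **not** separated by missing data are the method's hard
case: following them needs a window narrow enough to defeat the purpose
of the wide filtering step. If such shifts are small, the practical
recourse is a larger dive-detection threshold downstream.

### Correction sign and clamping

The surface estimate runs through the *middle* of the residual surface
noise (a $p$-quantile of it), so corrected surface readings straddle
zero and the minimum corrected depth is negative. If the error is
symmetric, negative corrected depths can be treated as error;
`clamp_negative = TRUE` zeroes them after subtraction. It is off by
default because it is an analyst's choice, not part of the method, and
it destroys the subtraction identity
`corrected + surface == input` that the unclamped output satisfies.
Depth is assumed positive downwards; records using the opposite
convention must be negated by the caller.

## Tunable parameters

| Parameter | Units | Default | Role |
|---|---|---|---|
| `k` | samples | — | window width per step; step 1 narrow (noise), last step wide (surface). Convert from seconds by dividing by the sampling interval. |
| `probs` | fraction | — | quantile per step; 0.5 first, then small (0.01–0.05 if little noise survives step 1, larger, e.g. 0.3–0.35, if much does). |
| `depth_bounds` | m | none | band where the surface is expected; essential with frequent deep diving. |
| `na_rm` | flag | `FALSE` | drop missing samples before filtering; only safe without level shifts under the gaps. |
| `clamp_negative` | flag | `FALSE` | zero negative corrected depths after subtraction. |

Four ready-made parameterisations for contrasting diving regimes ship
as YAML recipes (`list_recipes()`, `read_recipe()`): `turtle`
(1-s sampling, fine resolution, slight warm-surface artifacts),
`auklet` (3-s sampling, shallow frequent diving, shifts without gaps),
`penguin` (coarse resolution, unstable transducer, deep diurnal
diving) and `pilot_whale` (thermal hysteresis, three steps). Window
widths in recipes are stored in samples at the recipe's stated sampling
interval and must be re-scaled for other instruments. The recipes are
documentation of practice, not tested claims about any particular
data set.

## The synthetic experiment

Real deployments do not come with ground truth, so the package
evaluates itself on simulated records where the truth is known.

`simulate_dives()` generates a clean record: bouts of piecewise-linear
descent–bottom–ascent dives separated by surface intervals, a longer
pause between bouts, and a dry (hauled-out) period splitting the record
into two trips. The surface is *exactly* 0 there by construction. The
defaults define the package's standard experiment: 60,000 samples at
5 s (~3.5 days), dives of 10–80 m, surface intervals of 1–10 min,
eight dives per bout, 20–40 min between bouts, dry period over the
middle tenth. Dive-phase durations (descent and ascent 20–60 s, bottom
10–90 s) were chosen once as realistic for a medium-sized otariid and
are not tuned; dive-shape realism is deliberately out of scope because
the filter only ever sees the surface signal — depths beyond the
surface band influence nothing but the interpolation endpoints (a
property the test suite asserts bit-for-bit).

`corrupt_tdr()` then applies operators in order: `op_noise(sigma)`
(i.i.d. Gaussian on every sample), `op_drift(start, end, delta)` (a
linear ramp from 0 to `delta` across the span), `op_shift(start, end,
offset)` (a constant offset) and `op_gap(start, end)` (missing run).
`benchmark_corrupt()` wires them into the standard recipe: gap at
samples 36,000–42,000 (carried by the clean reference too — those
samples are unobserved, full stop), noise with $\sigma = 1$ m
everywhere, drift to −2 m over samples 8,000–36,000, shift of +3 m over
samples 36,000–60,000. The drift and shift spans share sample 36,000,
where both apply — preserved as-is and noted here; the shared sample
lies inside the gap, so the level transition is hidden from the filter,
which is exactly the configuration the gap semantics exist for.

Seeding: one integer seed drives the simulator and another the noise
draw, through R's default RNG; identical seeds give bit-identical
records. The experiment is reproducible distributionally, not as any
particular historical noise vector.

What passing this experiment does **not** show: the simulator has no
thermal hysteresis, no depth-resolution quantisation, no irregular
sampling, and drift that is linear rather than temperature-shaped. Real
records fail in all four ways; the recipes above are the accumulated
practice for them, and performance there is qualitative, not certified
by these tests.

## Evaluation statistics

With the clean record $o_t$ in hand, `evaluate_correction()` reports

$$\mathrm{RMSE} = \sqrt{\frac{1}{n}\sum_t (c_t - o_t)^2}$$

over the $n$ jointly non-missing samples ($c_t$ the corrected depth),
plus summary statistics of the deviations $c_t - o_t$ and a one-sample,
two-sided Kolmogorov–Smirnov test of the deviations against
$\mathcal N(0, \sigma^2)$, the distribution they would follow under a
perfect correction. The asymptotic KS p-value is used — sample sizes
here are in the tens of thousands, where the exact computation buys
nothing. Pairwise deletion is the missing-data policy throughout, and
`n_compared` makes it visible in the report.

A correction that works drives the RMSE down to the injected noise
scale $\sigma$, since the noise itself is not removable by an offset
estimate. On the standard experiment the two-step filter
`k = c(12, 720)`, `probs = c(0.5, 0.35)`, `depth_bounds = c(-6, 8)`
lands within a few percent of $\sigma = 1$ m (the acceptance script,
`scripts/acceptance.R`, recomputes this from scratch). The KS test, at
these sample sizes, still rejects normality: the deviations carry
small systematic structure near level-shift transitions and dive edges.
That is expected — the statistic is reported to *quantify* the
residual difference, not as a gate the correction must pass.

```{r experiment}
clean <- simulate_dives(seed = 1)
both <- benchmark_corrupt(clean, sigma = 1, seed = 2)
corrected <- correct_depth(both$corrupted, k = c(12, 720),
                           probs = c(0.5, 0.35), depth_bounds = c(-6, 8))
evaluate_correction(both$clean, corrected, sigma = 1)
```

The fit behind a corrected record is a first-class object:

```{r fit}
fit <- zoc_fit(corrected)
fit
tidy(fit)
glance(fit)
```

`augment(fit)` (or `write_filter_csv()`) exposes the full per-sample
stack — input, each step's output, surface, corrected — and
`autoplot(fit)` draws the three-panel input/filters/corrected picture;
`autoplot()` on the evaluation overlays the deviation density on the
reference Gaussian.

## Numerical and degenerate-input choices

* Interpolation over out-of-band runs is linear in sample index
  (equivalently in time, given regular sampling); runs touching a
  record end take the nearest in-band value rather than extrapolating a
  trend.
* A step with *no* in-band samples is an error — there is nothing to
  anchor the surface — as is an all-missing comparison in the
  evaluator.
* Irregular sampling is tolerated with a warning and never resampled:
  windows are index-based, so the analyst must judge whether "k
  samples" still means what they intend.
* An all-missing window yields a missing filter output; with bounds
  set, such positions are filled by the same interpolation as
  out-of-band ones.
* Record subsetting and all corruption spans are 1-based and inclusive
  at both ends.

## Problem sizes in the checks

The randomized oracle comparison runs a thousand instances of length up
to 200 with windows up to 25; the benchmark RMSE experiment runs five
seeds at the full 60,000 samples; supporting property tests use records
of 1,500–12,000 samples. These sizes make the whole suite run in tens
of seconds while leaving the headline experiment at its natural scale.

## Known limitations

* Window widths and quantiles are user-chosen; nothing is data-adaptive.
* Level shifts without separating gaps cannot be followed exactly
  (inherent to fixed windows, as analysed above).
* The simulator's realism limits are listed above; conclusions about
  instrument-specific behaviour need real records.
* One quantile per pass: multi-probability passes and weighted or
  asymmetric windows are out of scope.
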