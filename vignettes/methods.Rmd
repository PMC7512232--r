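---
title: "Detecting deterministic structure in eye-movement velocity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting deterministic structure in eye-movement velocity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oculochaos)
```

## The problem

During a fixation the eye is never still: tremor, drift and microsaccades
keep the gaze in constant micro-motion. Whether this micro-motion is best
described as filtered noise or as the output of a low-dimensional
deterministic (possibly chaotic) system is an open question in oculomotor
research. `oculochaos` implements the standard nonlinear-time-series toolkit
for asking that question of fixational velocity signals recorded during a
"jumping point" protocol: a dot appears at a sequence of screen locations
(29 by default), each shown for 3000 ms, while a 1000 Hz eye tracker records
horizontal gaze position.

The analysed objects are *velocity* series: each 3000-sample fixation-locked
position segment is differentiated by the two-point forward difference,
giving 2999 velocity samples, and analysed both before ("BNR") and after
("ANR") noise reduction by an ideal (brick-wall DFT) low-pass filter with a
50 Hz cutoff. With 48 recorded sessions this yields 48 x 29 = 1392 series
per condition.

## Phase-space reconstruction

A scalar series `x_1..x_N` is embedded as delay vectors
`y_i = (x_i, x_{i+tau}, ..., x_{i+(m-1)tau})` (Takens reconstruction). Two
parameters must be chosen per series:

* **Time lag `tau`** — from the average mutual information (AMI) profile
  `I(tau)`, estimated on a 2-D histogram with Freedman–Diaconis bin width
  `2 IQR n^(-1/3)`. The selection rule is the field's convention: the first
  strict local minimum of `I`; if the profile has none, the first lag where
  `I` falls below `I(0)/e`; failing both, the largest scanned lag with a
  warning. The rule actually applied is recorded on the result, because the
  choice is a convention, not a theorem.
* **Embedding dimension `m`** — from the false-nearest-neighbour (FNN)
  fraction: a neighbour is false when the extra-coordinate ratio
  `|x_{i+m tau} - x^{NN}_{i+m tau}| / ||y_i - y^{NN}_i||` exceeds a
  threshold `R` (default 10); the smallest `m` whose false fraction drops to
  1% is selected. Neighbour pairs closer than `1e-7` times the series range
  are excluded as duplicates: for noise-free periodic signals, revisits of
  the same state differ only by floating-point roundoff and the ratio of two
  roundoff-scale distances is meaningless. For the cohort pipeline the
  dimension is not selected per series; the correlation analysis simply
  scans `m = 3..15`, which brackets any selection this data could produce.

## Correlation sum, D2 and the Theiler window

The Grassberger–Procaccia correlation sum `C(m, r)` is the fraction of
embedded vector pairs within distance `r`, restricted to pairs at least
`w + 1` samples apart in time (Theiler window, default `w = 100` per the
protocol; the space–time separation plot in `space_time_separation()` /
`suggest_theiler()` justifies the choice per series). Pair counting sorts
each pair into a radius bin and accumulates, so one pass over the pairs
answers the whole 100-point log-spaced radius grid
(`r` in `[sd/10, 10 sd]`) for every `m` at once; the result is bit-identical
to naive enumeration, which the tests assert on hundreds of random
instances.

The correlation dimension D2 is the slope of `log C` vs `log r` in the
scaling region. Per `m >= 3` the slope is fit by least squares inside the
region; the reported value is the median over the *m-plateau*, the longest
run of dimensions whose successive slopes differ by less than 0.2. A
deterministic series shows such a plateau; a stochastic one shows slopes
that keep growing with `m`, and the estimate carries
`plateau_found = FALSE`. This aggregation is our operationalisation of what
is usually done by visual inspection of the slope curves; inspecting
per-series plots remains possible via `plot()` on the `corr_sum` object and
the `per_m` table of every estimate.

Scaling regions: the per-condition defaults are `r` in `[0.00055, 0.0018]`
(BNR) and `[0.001, 0.003]` (ANR), in the velocity units (deg/ms) of the
recordings the protocol describes. The BNR pair is taken from the stated
log10 bounds (-3.26, -2.74) of the region rather than the inconsistent
linear pair sometimes quoted with them; both are reachable through
configuration. A fixed absolute region presumes a particular velocity
scale, which synthetic or re-recorded data need not match; when the
configured region intersects fewer than 3 usable radii, `estimate_d2()`
falls back to an automatically detected region — the radius window where
the local slopes are jointly flattest across `m` — and flags the fallback
in the manifest. Data-length limits follow `D2 <= 2 log10 N`: 2999 samples
support estimates up to about 7, and 1000 samples up to 6, which is why the
pipeline also analyses 1000- and 1500-sample prefixes.

## Correlation entropy K2

`K2(m, r) = ln( C(m, r) / C(m+1, r) )`, the rate at which neighbours are
lost when one more delay coordinate is added. It is defined in the joint
limit `r -> 0`, `m -> infinity`: the implementation honours the `r` side by
averaging over the smallest few radii at which every consecutive pair of
dimensions still has support (below saturation), and the `m` side by taking
the median over the plateau of `K2(m)` values, preferring the largest-`m`
run on ties. Signatures, all asserted in the tests: ~0 for a periodic
signal, positive and finite for a chaotic one (Henon: ~0.3–0.5 nats per
embedding step), large and growing with `m` for white noise. Per the
protocol, K2 is evaluated in three fixation windows — `<1...700>`,
`<700...1500>`, `<1500...2999>`, 1-based inclusive as printed, so adjacent
windows share one boundary sample (lengths 700/801/1500) — tracking how the
information rate evolves from the saccade-landing transient into quiet
fixation.

## Largest Lyapunov exponent

`lle_rosenstein()` implements the Rosenstein divergence-curve method: each
vector's nearest neighbour under Theiler exclusion seeds a pair whose log
distance is tracked forward; the slope of the mean log-divergence curve
over its initial rise (fit up to 80% of the curve's total rise by default,
or an explicit step range) divided by the time step is the exponent.
Zero-distance pairs are excluded, never divided by. On the Henon map the
estimate lands in the literature band (~0.42 per iterate); on a sine it is
numerically zero.

## Surrogate testing

The linear-stochastic null is embodied by FFT surrogates: DFT amplitudes
kept exactly, phases randomised with Hermitian symmetry (DC and Nyquist
fixed), so spectrum, mean and autocorrelation survive while any
deterministic structure is destroyed. The decision rule operationalises
"the surrogates' dimensions did not converge": reject the null when the
original shows an m-plateau while at least `k = 4` of 5 surrogates do not.
Failed surrogate analyses are excluded and `k` is re-based
proportionally. The rule's qualitative ancestor is a visual judgement; the
plateau criterion makes it reproducible, and `k` is configurable.

## The synthetic cohort

`generate_session()` emulates the jumping-point experiment so every stage
runs without recordings: per stimulus, the gaze holds its previous position
for a saccadic latency drawn uniformly from one of the three reported
latency bands (90–120, 135–170, 200–220 ms; band chosen uniformly, the
bands being reported without probabilities), moves along a minimum-jerk
profile of 40 ms (saccade kinematics are not the object of study; any
smooth monotone profile serves), then fixates with a random-walk drift
(increment sd 5e-4 deg/sample), a tremor sinusoid with frequency drawn from
60–100 Hz (deliberately above the 50 Hz cutoff so the BNR/ANR contrast is
non-trivial) and amplitude 0.01 deg, plus white measurement noise of 0.01
deg sd (flat to Nyquist, typical of infrared oculography). Screen geometry
(370 x 295 mm at 450 mm, ~40 x 32 deg) converts universal-scale
coordinates to degrees via `atan`; the mapping is configuration, since
protocols differ. Everything is a pure function of `(params, seed)`.

What the generator does *not* emulate: microsaccades, saccadic under- and
overshoot corrections, drift with attractor dynamics, blink artifacts, or
any genuinely chaotic fixational core. Passing tests on this cohort
therefore validate the *pipeline* — counting, filtering, estimation,
significance machinery — not any claim that real eye movements are chaotic;
estimator validity is established separately on the canonical reference
systems (`generate_reference()`: Henon, Lorenz via fixed-step RK4, sine,
white noise, AR(1)) whose invariants are known.

## Numerical choices and degenerate inputs

* The Heaviside counting convention is `distance <= r`; squared distances
  are compared against squared radii, which is exact.
* The filter keeps the bin at exactly the cutoff frequency (zeroing only
  strictly above); it preserves the mean to machine precision and is a
  projection (idempotent).
* The AMI histogram refuses constant series (zero IQR); ties in
  nearest-neighbour searches break to the smallest index.
* Exact Wilcoxon signed-rank p-values are computed by convolution over the
  (possibly tied, average-rank) rank multiset for `n <= 25` retained
  differences — exact even with ties, which the usual implementations
  approximate — and by the tie-corrected continuity-corrected normal
  approximation above; zero differences are dropped, and an all-zero
  comparison reports `p = 1` with a degeneracy flag. The Shapiro–Wilk gate
  is reported, not branched on, matching the protocol's use of it to
  justify the rank test.
* No multiple-testing correction is applied to the per-session p-values;
  the report layer mirrors raw `p < 0.05` percentages.

## Problem sizes

The cohort analyses in the examples, tests and acceptance script run 2–4
synthetic sessions (58–116 fixation series per condition) with the full
default parameter set (m = 3..15, 100 radii, Theiler 100, lengths
1000/1500/2999, three windows, 5 surrogates on a 3-fixation subsample per
session), which exercises every stage at the protocol's native series
length of 2999 samples. Estimator-validation runs use N = 2000–5000 for the
reference systems, the range in which their literature invariants are
customarily reproduced. A 48-session cohort is the same computation
repeated; `simulate_cohort()` + `run_pipeline()` scale linearly in the
session count.

## Known limitations

* Fixed per-condition scaling regions are a convenience with a documented
  fallback, not a principled per-series choice; serious use should inspect
  `per_m` slopes and the `region_fallback` flags.
* FNN without Kennel's second (attractor-size) criterion understates false
  neighbours for pure noise at larger `m`; the package reports the profile
  for the documented single-ratio rule.
* K2 from finite data at small radii is biased upward by measurement noise;
  BNR values especially should be read as noise-floor entropies.
* The surrogate decision is a screening rule with `k` of 5 surrogates, not
  a calibrated hypothesis test with a stated size.
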