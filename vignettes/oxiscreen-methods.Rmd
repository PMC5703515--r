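---
title: "Methods: oximetry-based screening for moderate-to-severe sleep apnea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: oximetry-based screening for moderate-to-severe sleep apnea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`oxiscreen` estimates the apnea–hypopnea index (AHI, events per hour) of a
subject from a single overnight SpO₂ channel sampled at 1 Hz by a portable
finger oximeter, and provides the agreement and diagnostic statistics used
to judge such an estimator against polysomnography (PSG). This vignette is
the package's own account of the science: the model and its assumptions,
every tunable that matters, what the synthetic generator does and does not
emulate, the numerical choices, and the limits of what passing tests show.

## The signal model

Obstructive apneas and hypopneas produce repetitive oxygen desaturations:
falls of a few percentage points over tens of seconds, followed by
resaturation when breathing resumes. The method assumes that

* disease severity is encoded in the *statistics* of the overnight SpO₂
  profile — its amplitude distribution, its spectral content in the band
  of apneic recurrence, and its irregularity — rather than in any single
  event;
* the recording is long enough (validity requires a total recording time
  of at least 4 h; shorter portable recordings are rejected with reason
  `"TRT<4h"`, computed on the raw series as `(n-1)/rate` before artifact
  removal, with exactly 4 h valid because the exclusion is a strict `<`);
* artifacts are short and extreme (zeros, physically impossible values,
  instantaneous jumps), while genuine physiology changes slowly — deep
  but gradual desaturations, including the sustained hypoxemia of chronic
  obstructive pulmonary disease (COPD), must survive cleaning.

## Preprocessing

Three artifact rules, applied in order, with missing samples treated like
zeros:

1. zeros and samples below 20% saturation are removed;
2. the remaining series is split at every step with |Δ| ≥ 4 %/s; a run
   flanked by such steps is deleted when it is shorter than 30 s *and*
   shorter than its neighbour (the shorter of the two locally consistent
   runs). Runs of 30 s or more on both sides of a step are kept as
   physiology: a persistent level shift is a real desaturation plateau,
   not a movement artifact. The 30 s threshold (`min_run`) and the 4 %/s
   limit (`delta`) are arguments of `remove_artifacts()`;
3. at each concatenation seam that still jumps by ≥ 4 %/s,
   `bridge_gaps()` inserts the *fewest* equally spaced samples such that
   every step is strictly below 4 %/s (k intermediates, k the smallest
   integer with |Δ|/(k+1) < 4). A seam of exactly 4 therefore gets one
   intermediate sample; a 16-point seam gets four. The strict inequality
   is deliberate: a step of exactly 4 %/s is, by rule 2, an artifact, so
   the bridged output must not contain one. The pipeline output is
   consequently free of zeros, sub-20% values, missing samples and
   ≥ 4 %/s steps, and preprocessing an already-clean signal is the
   identity.

Which side of an instantaneous step is the artifact is genuinely
undecidable from the signal alone; the shorter-run rule encodes the prior
that transients are artifacts and plateaus are physiology, and both
thresholds are exposed for sensitivity analysis.

## The 16 features

Time-domain and nonlinear measures are computed on non-overlapping
512-sample segments (trailing remainder discarded; a recording needs at
least 512 clean samples) and averaged arithmetically across segments —
how per-segment values become one number is a convention of this package;
the mean is the simplest estimator of the per-segment expectation.
Spectral measures come from one whole-recording Welch periodogram.

* **M1t–M4t** — mean, variance, skewness, standardized kurtosis of the
  saturation histogram (%, %², unitless, unitless). Kurtosis is the raw
  standardized fourth moment (Gaussian → 3), not excess; skewness and
  kurtosis of a constant segment are defined as 0.
* **Welch PSD** — 512-sample Hann window, 50% overlap, 1024-point FFT,
  one-sided density scaling, each window mean-detrended. Detrending makes
  the estimate describe saturation *fluctuations* and gives Parseval a
  meaning (`sum(psd)·Δf ≈` variance of the detrended signal, checked to
  5% in the tests); it also makes every feature except M1t invariant to
  adding a constant to the signal, an asserted property.
* **M1f–M4f** — moments of the histogram of normalized PSD amplitudes
  (PSD scaled to unit sum, moments taken over the bin values). The
  alternative reading — frequency-weighted spectral moments — is a
  different quantity; the amplitude-histogram form was chosen because it
  mirrors the time-domain construction, and the PSD object is exposed so
  the other form is one line of user code.
* **MF, SE** — median frequency (smallest frequency reaching 50% of
  cumulative power) and spectral entropy (Shannon entropy of the unit-sum
  PSD divided by log of the bin count, so flat → 1, one-hot → 0).
* **P_T, PA, P_R** — total integrated power (%²), peak PSD amplitude and
  relative power in 0.014–0.033 Hz (bounds inclusive). Desaturation
  cycles of roughly 30–70 s put apneic recurrence in this band.
* **SampEn(m = 1, r = 0.25·SD)** — irregularity; the tolerance uses the
  standard deviation of the whole preprocessed recording, so segments
  share one scale and the measure is shift-invariant. −ln(A/B) with
  template matches counted over n−m starting points, self-matches
  excluded; B = 0 (no matches) returns 0 with a warning, and A = 0 is
  capped at −ln(1/B).
* **CTM(ρ = 0.25%)** — fraction of second-order difference points
  strictly inside the radius-ρ circle; near 1 for low variability.
* **LZC** — LZ76 phrase count of the median-binarized segment, normalized
  by n/log₂(n); a constant segment parses into two phrases, random
  sequences approach 1.

m, r, ρ, the binarization threshold, the segment length and the spectral
band are all function arguments; the defaults above are the package's
single fixed choice, stated here once and not tuned per dataset.

## Feature selection (FCBF)

Entropies need discrete variables; features and the continuous reference
AHI are discretized by equal-frequency binning into 4 bins (rank-based,
ties broken stably by position, constant vectors collapse to one label).
Equal-frequency binning is robust to the strongly right-skewed AHI
distributions of sleep-clinic cohorts and makes the selection invariant
to monotone transforms of any feature. Relevance ranks features by
symmetrical uncertainty SU with the binned AHI (no threshold beyond
SU > 0 — pruning is the redundancy stage's job); redundancy scans the
ranking from the top and removes any lower-ranked j with
SU(i, j) ≥ SU(j, AHI). Ranking ties keep original column order, so the
result is deterministic and invariant to subject order.

On clean synthetic cohorts the filter is aggressive — often one or two
features survive, because a single variance-like feature carries nearly
all the information about the implanted event rate. On clinical data the
published subsets retain 9 (in-lab) and 8 (at-home) of the 16; both are
shipped as presets (`osas_presets()`).

## The regression network

A single hidden layer of `N_H` tanh units and a linear output floored at
0 (the AHI is a nonnegative rate). Training minimizes
`Σ(y − f(x))² + ν(‖ω_in‖² + ‖ω_out‖²)` — weight decay on connection
weights, biases unpenalized so the penalty-dominated limit can still match
`mean(y)` — by BFGS with analytic gradients, relative tolerance 1e−8, at
most 500 iterations. Inputs are z-scored with training-set statistics
stored in the model; initial weights are uniform ±0.5 scaled by fan-in
from a caller-supplied seed, so training is bit-reproducible. Model
selection runs repeated leave-one-out cross-validation over a grid
(defaults N_H ∈ {2,4,…,20}, ν ∈ {0.1,0.5,1,2,4,8} — the package's own
grid), scores each cell by mean ICC between held-out estimates and the
reference AHI across repetitions (default 100, matching the published
protocol), and breaks ties toward smaller N_H, then larger ν — the
simpler, more regularized model. A constant reference AHI makes the ICC
metric undefined and is an error. Per-fold and per-repetition seeds are
derived deterministically from the caller's seed by a 32-bit linear
congruential mix, so any two runs with the same seed agree exactly.

## Desaturation indices

The source studies report ODI3/ODI4 from the oximeter's own software
without defining the algorithm, so the package's detector is a documented
stand-in built from standard scoring conventions, and no agreement with
device-reported ODIs is claimed. Its one structural guarantee is worth
stating: candidate episodes are delimited *independently of the depth
threshold* (runs where a 10-s moving average sits ≥ 1% below the 120-s
moving-maximum baseline, runs closer than 10 s merged, depth scanning
capped at 300 s), and an episode counts at threshold t iff its maximum
raw drop reaches t. Event counts are therefore monotone in the threshold,
so ODI4 ≤ ODI3 holds for *every* recording — a property an
episode-per-threshold definition cannot guarantee (two 4% dips linked by
a 3.5% valley would count once at 3% but twice at 4%). Episode
delimitation uses the smoothed series because a moving maximum of the raw
signal rides about one noise-SD above the resting level and, at realistic
noise, merges the whole night into a single episode; depth is still
measured on the raw series so shallow events are not attenuated away.
CT90 is the percentage of samples below 90%; basal SpO₂ is the modal
integer saturation (`basal = "median"` switches convention).

## Agreement and diagnostic statistics

ICC defaults to the single-measure, absolute-agreement, two-way
random-effects coefficient with the F-based confidence interval;
`variant = "consistency"` is available, and the default was kept because
an AHI estimator that is systematically offset *should* be penalized in a
screening context. Bland–Altman reports bias = mean(estimate − reference)
and limits bias ± 1.96·SD with width 2·1.96·SD — the "confidence
interval" figure quoted alongside published Bland–Altman plots is read as
this width. The mountain plot folds empirical percentiles
100·r/(n+1) at 50%. Dichotomizing both AHIs at 15 or 30 events/h gives
Se/Sp/PPV/NPV/accuracy (Wald CIs, switching to Wilson when a cell count
is below 5 — the CI method behind the published tables is not stated, so
these CIs are the package's choice and only point estimates are checked
against print), likelihood ratios with log-method CIs and LR+ flagged
undefined when Sp = 100%, and AUC by the Mann–Whitney rank identity with
a Hanley–McNeil CI.

## The synthetic generator

`simulate_recording()` builds baseline + events + noise, clipped to
[50, 100]:

* resting saturation 94% (91% in COPD mode), matching the basal levels of
  the two published test groups;
* trapezoidal desaturations — linear fall over 20–40 s, 5 s nadir hold,
  15 s resaturation, depth Normal(5, 1) truncated below at 3% — arriving
  as exponential-gap renewals with a 10 s hard core so events never
  overlap; the *realized* event times are the ground truth and the
  realized rate is the recording's true AHI surrogate. Rates above ~60/h
  leave no room between events and raise an "infeasible" error;
* Gaussian measurement noise, SD 0.5% by default;
* COPD mode adds sustained hypoxemic epochs (2–4% below baseline,
  10–30 min long, roughly 40% of the night, one-minute entry/exit ramps),
  reproducing the published contrast between groups: high CT90 with basal
  91% versus low CT90 with basal 94%, without changing the event rate;
* `inject_artifacts()` corrupts a clean recording with the three artifact
  classes at a controlled rate, ≥ 5 s apart, so preprocessing reports can
  be checked against known injections;
* `simulate_cohort()` draws true AHI uniformly on 0–60 events/h and, for
  paired designs, regenerates the home night with the rate multiplied by
  a mean-one lognormal factor (sdlog 0.35) — night-to-night variability
  is the dominant published explanation for the in-lab → at-home
  agreement drop, and the generator reproduces exactly that ordering.

What the generator does *not* emulate: oximeter quantization and
averaging filters, pulse-artifact structure correlated with events,
central/positional apnea patterns, REM-stage clustering of events, or any
gas-exchange physiology. Passing tests therefore demonstrate the
*internal correctness* of every stage and the recoverability of a known
signal model — near-perfect cohort ICCs on synthetic data bound the
method from above and must not be read as clinical performance, which on
real recordings is materially lower (ICC ≈ 0.94 in-lab, ≈ 0.73–0.79 at
home in the source validation).

## Problem sizes and numerics

The test suite uses cohorts of 12–60 subjects with 0.5–4 h recordings for
unit-level properties, a 200-subject, 4 h-per-night cohort for the
end-to-end parameter-recovery check (held-out ICC ≥ 0.8), 1000 quarter-hour
recordings for the ODI monotonicity sweep, and brute-force oracle
comparisons on 100–500-sample series; these sizes are the package's
choices balancing statistical resolution against a test run of a few
minutes. Degenerate inputs are handled explicitly: empty spectra,
constant series (entropy and discretization collapse gracefully; ICC on
two constant vectors is an error), recordings emptied by cleaning
("unusable recording"), single-class labels for AUC, and zero-duration
recordings for ODI.

## Known limitations

* The published network weights are not reproducible — the training
  cohort was never released — so the shipped presets carry the published
  architecture, not the published parameters; any quantitative claim in
  this package is about recovery of synthetic ground truth.
* The ODI detector is a stand-in for an undocumented device algorithm;
  its absolute values should not be compared against device-reported
  ODI columns.
* EDF support is minimal (16-bit EDF, 1 Hz SpO₂ channel located by
  label); clinical EDF+ annotations and other sampling rates are out of
  scope.
* Equal-frequency discretization with 4 bins is one defensible choice;
  FCBF subsets can change under a different bin count, which is why the
  bin count is an argument.
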