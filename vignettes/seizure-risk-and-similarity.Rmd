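---
title: "Seizure risk and seizure similarity: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seizure risk and seizure similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ictal)
```

This vignette documents the statistical models behind `ictal`, the
parameters that matter, the numerical conventions, and what the bundled
synthetic data can and cannot demonstrate.

## The experimental frame

All analyses assume a cohort of injection experiments on epileptic
animals, each aligned at the start of the first injection (t = 0) and
observed from 3 h before to 5 h after.  The baseline window is
`[-10800, 0)` s and the experimental window `[0, 10800)` s; every window
in the package is half-open, `[t0, t1)`, so counts over a partition add
up to the total.  Seizures enter the risk statistics as point events at
onset — durations are carried in the data model but deliberately ignored,
because the scientific question is how often seizures *start*, not how
long they last.

## Seizure rates and the two chi-square statistics

Seizure initiation is modelled as a Poisson process, so the variance of a
count equals the count.  Two distinct 1-df chi-square statistics follow
from this and are kept as separate operations because they answer
different questions:

* `poisson_rate_test()` compares two *counts over equal exposures*:
  `chi2 = (n1 - n2)^2 / (n1 + n2)`.  The closed form is only valid for
  equal exposures, so unequal exposures are rejected rather than
  silently approximated.  Both counts zero is defined as
  `chi2 = 0, p = 1` (no evidence of any difference).
* `proportion_test()` compares two *classified proportions* `p_i = k_i /
  n_i` whose Poisson uncertainties are `u_i = sqrt(k_i)/n_i`:
  `chi2 = (p1 - p2)^2 / (u1^2 + u2^2)`.  Note the scaling behaviour,
  which is a property of the uncertainty model rather than a bug: mapping
  `(k, n)` to `(ck, cn)` leaves the proportions unchanged but multiplies
  the statistic by `c`, because more classified seizures mean tighter
  Poisson uncertainties.  When both uncertainties vanish (`k1 = k2 = 0`)
  the test returns `p = 1` if the proportions agree and `p = 0`
  otherwise.

Upper-tail p-values come from the chi-square distribution via R's
`pchisq()` (i.e. the regularized incomplete gamma function).

## The kernel-smoothed Nelson–Aalen hazard

The hazard — the instantaneous seizure rate among experiments currently
able to seize — is estimated by smoothing the Nelson–Aalen increments
with an Epanechnikov kernel `K(u) = 0.75 (1 - u^2)` on `|u| <= 1`:

$$\hat h(t) = \sum_i \frac{K_b(t - T_i)}{Y(T_i)}, \qquad
  \widehat{\mathrm{var}}(t) = \sum_i \frac{K_b(t - T_i)^2}{Y(T_i)^2},$$

with `K_b(u) = K(u/b)/b` and bandwidth `b = 5 / sqrt(N)` hours, `N` being
the number of contributing events.  The bandwidth shrinks with more
events, trading smoothness for resolution in the usual `1/sqrt(N)` way.

**The at-risk rule.**  `Y(t)` counts experiments with no seizure onset in
the *open* interval `(t - 300 s, t)`.  Openness at both ends matters:

* open at `t`: an onset exactly at `t` does not remove its own
  experiment, so every first event of a burst sees `Y >= 1` and the
  estimator's increments are well defined;
* open at `t - 300 s`: an experiment re-enters the risk set exactly five
  minutes after an onset, keeping the rule consistent with the episode
  exclusion below.

**Episode merging.**  Onsets within 300 s of the previous *kept* onset in
the same experiment are treated as a continuation of the same ictal
episode: they are excluded from the hazard event set (with a warning) and
from `N`.  They still count in `mean_rate()`, which deliberately counts
all annotated onsets.  With this pairing of exclusion rule and risk-set
rule, the estimator remains unbiased for a homogeneous Poisson cohort —
the events removed are exactly those occurring while the experiment is
out of the risk set — which the test suite verifies by simulation
(`lambda` of 0.25, 0.5 and 1.0 seizures/h, 200 experiments per cohort,
interior time average within three Monte-Carlo standard errors).

**Grid and boundaries.**  The curve is evaluated on a 1-minute grid over
`[-3, +5]` h by default — fine enough that the divergence argmax is
stable.  No boundary correction is applied: kernel mass falling outside
the observation window is dropped, so the hazard is biased low within one
bandwidth of −3 h and +5 h.  This is documented rather than corrected
because the quantities of interest live in the interior.

**Divergence from baseline.**  `max_divergence_time()` scans `t >= 0` for
the maximum of `(ĥ(t) - rate)^2 / (var(t) + uncertainty^2)`, where the
baseline is the pooled `[-3, 0)` h rate (a flat reference, matching how
average pre-injection risk is usually displayed) rather than a smoothed
baseline hazard.  Two deliberate choices:

* Grid points within one bandwidth of the upper window edge are excluded
  from the scan by default.  Simulation shows that otherwise the
  edge-bias region — where both the hazard and its variance estimate are
  biased low — captures the argmax in roughly a third of elevated-cohort
  replicates, reporting a spurious late divergence.
* The returned p-value is the chi-square tail at the *selected* time.
  Because the time is chosen as the argmax over many correlated grid
  points, this is an optimistic, multiplicity-uncorrected summary: in
  null simulations it falls below 0.05 in roughly half the replicates.
  It should be read as a ranking statistic ("where is the risk most
  different"), not a calibrated test; the calibrated comparison of
  baseline versus experimental risk is `poisson_rate_test()` on the
  window counts.  The tests therefore assert discrimination (elevated
  cohorts yield far smaller argmax p-values than null cohorts, and the
  argmax lies inside the injection window plus one bandwidth), not null
  calibration.

## The 44-feature seizure descriptor

Fourteen features are computed in each of three windows — the whole
seizure, its first 10 s, and its last 10 s (clipped to the seizure length
when shorter, in which case the three windows coincide): alpha
(8.5–13 Hz), beta (13–30 Hz) and gamma (30–128 Hz) band power, the
alpha–delta ratio, peak frequency, line length, positive and negative
spike counts, median inter-spike intervals and median spike amplitudes,
and the mean and SD of the Teager–Kaiser energy
`psi[n] = x[n]^2 - x[n-1] x[n+1]`.  Delta power (0.5–4 Hz) is computed
only in the first 10 s — later it is dominated by movement artifact — and
seizure length once, giving `14 * 3 + 2 = 44` features.  This is the only
arithmetic consistent with excluding delta elsewhere while keeping the
ratio features; the alpha–delta *ratio* is computed in all three windows
(its internal delta denominator is not exported as a feature).  The
deliberate 4–8.5 Hz gap between delta and alpha is preserved; no theta
band is computed.

Numerical conventions, all chosen for determinism and absence of NaN in
the downstream PCA:

* **PSD**: Welch's method — mean subtraction, Hann window, 1-s (256
  sample) segments, 50% overlap, 2× zero padding (0.5 Hz bins).  Windows
  shorter than one segment fall back to a single periodogram with a
  logged message.  Bands integrate the density over `[lo, hi)` so
  adjacent bands never double-count a bin; the gamma upper edge (128 Hz)
  is the Nyquist frequency at 256 Hz and that bin is included.
* **Peak frequency**: PSD argmax within `[0.5, 128]` Hz; ties — including
  the all-zero signal — resolve to the lowest in-range bin (0.5 Hz).
* **Alpha–delta ratio**: capped at 10^6 when delta power underflows to
  zero (0/0 returns 0).
* **Spike detection** (no canonical algorithm exists, so the package uses
  a transparent robust rule): local extrema of the requested polarity
  exceeding `threshold_k = 4` times the robust SD (MAD × 1.4826) of the
  window, thinned greedily in descending amplitude subject to a minimum
  separation of 0.08 s (a refractory bound well below ictal discharge
  intervals).  Both parameters are configurable.  Sign-flipping the input
  exchanges the positive and negative trains exactly.
* **Spike-train imputation**: zero spikes yields interval = window
  length and amplitude = 0; one spike yields interval = window length
  and that spike's amplitude.

Morlet spectrograms use an analytic Morlet mother wavelet (6 cycles by
default) evaluated by FFT convolution at log-spaced frequencies over
0.5–60 Hz, on the seizure plus 10 s of context (zero-padded with a
warning when the trace has less).

## The similarity pipeline

Per animal: (1) z-score the 44 features using the mean and SD over that
animal's seizures — by default *all* of them, induced included, since the
normalization describes the animal, not a class; a `normalize_on =
"spontaneous"` switch covers the stricter reading — with zero-variance
columns set to 0 and their SD recorded as 1; (2) project onto the first
two principal components of the z-scored matrix (correlation-matrix PCA,
eigenvalue order, sign fixed by making each component's largest loading
positive); (3) fit a one-class SVM to the spontaneous seizures' PC
scores.

The one-class SVM uses the ν formulation with `nu = 0.05` — ν upper
bounds the fraction of training points left outside the support — and an
RBF kernel `K(x, z) = exp(-||x - z||^2 / s^2)` with scale `s = 50`
(coordinates divided by `s` before a unit-width Gaussian, no factor 2).
On z-scored PC coordinates, whose spread is a few units, `s = 50` makes
the kernel nearly linear and the decision region a single large smooth
blob; this is preserved as the reference behaviour rather than
"corrected", and both `nu` and the scale are configurable.  Fitting is
delegated to the libsvm solver (e1071) with KKT tolerance 1e-6; an
all-identical training set short-circuits to an everything-similar
fallback with a warning.  A seizure is "similar" when its decision value
is non-negative.

`similarity_report()` evaluates every seizure against its own animal's
model and against every other animal's model (all permutations pooled),
tabulating per group the similar proportion, its Poisson uncertainty, and
the chi-square p-value against the own-spontaneous gold standard.
Seizure selection (`select_seizures()`) mirrors the study design — first
two induced seizures, up to ten consecutive spontaneous seizures at least
3 h before or 6 h after an experiment — and can be bypassed by simply not
calling it.

## What the synthetic data emulates — and what it does not

`simulate_timeline()` draws each experiment from an inhomogeneous Poisson
process: rate `lambda0` outside the injection period and `lambda0 * m(t)`
during `[0, 3)` h, with a step or linear ramp, thinned by a 300-s
refractory rule that mirrors post-ictal recovery and matches the hazard
module's risk-set window.  Defaults (`24` experiments, `lambda0 = 0.28`/h,
step multiplier `48/20`) reproduce the rate regime of the bundled cohort
by construction.

`simulate_seizure()` builds spike-wave discharges: sharp biphasic (Ricker)
transients riding on a slow-wave chirp locked to the instantaneous
discharge rate, which sweeps linearly between the archetype's start and
end rates, over 1/f background, with 10 s of context.  The wave component
(80% of spike amplitude by default) carries the low-frequency power, so
the spectral peak tracks the discharge-rate trajectory as it does in
recorded spike-wave seizures.  Archetype defaults (rates of a few Hz,
amplitudes 300–700 µV against a 40-µV background, 40 ± 8 s durations,
8% within-animal jitter) were chosen once to give the feature battery a
realistic dynamic range relative to typical hippocampal depth-electrode
recordings.  `make_cohort()` spaces archetypes by a separation parameter
(rate offset with a proportional amplitude offset); separation 0 makes
animals exchangeable, and the default 1.5 Hz makes between-animal
differences comfortably larger than within-animal jitter.  Negative
controls distort the archetype: kainic-acid seizures are three times
longer with up-shifted rates; electrical ones are low-voltage fast
activity (one fifth the amplitude, 15–22 Hz).

What passing tests on this cohort demonstrate: that the pipeline
recovers known rate structure, that the estimator is unbiased under
homogeneous risk, and that classification separates archetypes whose
differences exceed within-animal variability.  What they do not
demonstrate: performance on real EEG — recorded seizures carry artifacts,
non-stationary backgrounds, electrode drift and within-animal
morphological diversity that no stationary archetype model reproduces, so
the published similarity proportions themselves are not reproducible from
simulation and are not asserted anywhere.

## Problem sizes and determinism

The test suite and the acceptance script scale their simulations to
what the estimators need, not more: 200-experiment cohorts (five
replicates per rate) for hazard recovery, 2000 count pairs for rate-test
calibration, a 4-animal × 14-seizure EEG cohort for the classification
properties, and 12 replicates per arm for the divergence discrimination
check.  Every stochastic step is seeded; identical seeds give bit-identical
timelines, seizures, feature tables and reports, and the command wrappers
write byte-identical outputs on reruns.

## Known limitations

* The hazard estimator has no boundary correction and its divergence
  p-value is multiplicity-uncorrected (both discussed above).
* `poisson_rate_test()` supports equal exposures only.
* The EDF support is deliberately minimal: one signal, 16-bit linear
  calibration, 1-s records with a zero-padded final record.
* The spike detector is a transparent stand-in; absolute spike counts are
  parameter-dependent and only meaningful relative to a fixed
  configuration.
* Single-channel analyses only; no artifact rejection, no multi-channel
  montages, no automated seizure detection from continuous recordings —
  annotated onsets/offsets are inputs.
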