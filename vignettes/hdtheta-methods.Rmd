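---
title: "Head-direction tuning and theta-cycle skipping: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Head-direction tuning and theta-cycle skipping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdtheta)
```

`hdtheta` analyses single-unit recordings from freely moving rats foraging in
open arenas. It answers three questions about a unit: does it carry a head
direction (HD) signal, does it carry a place signal, and is its spike timing
organised by the theta rhythm — in particular, does it fire on alternate
theta cycles ("theta-cycle skipping")? The package also contains a
ground-truth simulator so every estimator can be validated against known
parameters without any recorded data.

## The session model

A session is 20 minutes of position tracking in a 96 cm circular or
60 × 60 cm square arena, sampled at 50 Hz through two head-mounted LEDs
6 cm apart (tracker rate and LED geometry are fixture conventions; only the
LED difference vector matters downstream). Head direction at each sample is
the planar angle of the front-minus-back LED vector; position is the LED
midpoint.

The simulator (`simulate_trajectory()`) emulates pellet-chasing foraging as
a smooth random walk: running speed is an Ornstein–Uhlenbeck (OU) process
(mean 20 cm/s, sd 8 cm/s, relaxation 1 s), body turning rate another OU
process (sd 60°/s), and the path reflects specularly off the walls. Head
direction is simulated as its *own* OU-driven angular process (angular
velocity sd 160°/s, relaxation 0.4 s) on top of the body path. The
decoupling is deliberate: rats scan their heads largely independently of
their running direction, and the clockwise/counter-clockwise analyses need
substantial dwell beyond ±120°/s, which path curvature at realistic running
speeds would not provide. With these defaults a 20-min session covers
>95% of 2.5 cm spatial bins and all 72 directional bins, matching the
session-inclusion rules below.

What the simulator does *not* emulate: wall-following (thigmotaxis) beyond
what reflection produces, pauses and grooming bouts, anticipatory
spike-time shifts, theta phase precession, slow drift of preferred
directions, and spike-sorting artefacts. Passing tests therefore certify
the estimators against the stated statistical structure, not against every
property of real recordings.

Spike trains are inhomogeneous Poisson processes sampled by thinning, with
three intensity families:

* **HD cells** — von Mises tuning
  $\lambda(t) = b + a\,e^{\kappa(\cos(\theta(t)-\theta_p(t))-1)}$, where the
  preferred direction $\theta_p$ is rotated $+\delta/2$ during clockwise and
  $-\delta/2$ during counter-clockwise head turns to produce a controlled
  separation angle $\delta$.
* **Place cells** — Gaussian spatial tuning
  $\lambda(t) = b + a\,e^{-\lVert x(t)-c\rVert^2/2\sigma^2}$.
* **Theta / theta-skipping cells** —
  $\lambda(t) = r_0\,[1 + m_1\cos(2\pi f t) + m_2\cos(\pi f t)]$ with
  $f = 8.67$ Hz. The half-frequency term attenuates alternate theta cycles;
  $m_1 + m_2 \le 1$ keeps the intensity non-negative. Defaults
  $r_0 = 5$ Hz, $m_1 = 0.6$, $m_2 = 0.4$ give an autocorrelogram modulation
  ($m^2/2$: 18% and 8%) comparable to a moderately skipping unit. The
  additive half-frequency construction (rather than deleting cycles) mirrors
  the superposition model the fitter assumes, so recovery tests have an
  exact analytic target: frequency ratio 2 and jump factor
  $m_2^2/(m_1^2+m_2^2) \approx 0.31$.

Trains are memoryless — no refractory dead time is imposed — so a 5 Hz
Poisson train genuinely fails the refractory-period convention below
(~1% of intervals under 2 ms); that is a property of the generator, not a
defect of the check.

## Directional analyses

Tuning curves use 72 bins of 5°; each spike takes the heading of its nearest
tracker sample (no interpolation, matching the per-sample definition of
HD), and the rate in a bin is spikes over dwell. Directional analyses are
only performed when the session passes inclusion: at least 90% of in-arena
spatial bins visited and every directional bin sampled (`dwell > 0`; a
minimum-dwell variant would also be defensible, but sampling is judged by
any dwell here). For cross-unit averaging, curves are normalized to peak 1
and circularly shifted so the peak falls in the bin containing 180°.

The clockwise/counter-clockwise split assigns samples (and their spikes)
with angular head velocity ≥ +120°/s to CW and ≤ −120°/s to CCW — the sign
convention is fixed so that *positive is clockwise*, since screen
coordinates often invert it — and uses the visits-based rate (spikes per
visit to a bin) within each category, with the dwell-based rate retained
for the main curve; both conventions are labelled on the curve objects.
Angular velocity is a central finite difference of the unwrapped heading
with an optional 5-sample boxcar (on by default); the estimator is a
package choice, only the threshold is inherited.

Two estimator decisions matter and are worth stating plainly:

* **Preferred direction.** The argmax bin of a von Mises-shaped curve is
  bin-noise-dominated: neighbouring bins sit within a few percent of the
  peak, so the argmax wanders ±1–2 bins regardless of session length.
  `preferred_direction()` therefore uses the rate-weighted circular mean,
  which is unbiased for symmetric tuning and precise to about a degree at
  these spike counts. The argmax bin is still reported.
* **Separation angle.** Likewise computed as the circular difference of the
  two categories' rate-weighted mean directions, not their argmax bins; a
  20° generated offset is recovered to within 3° in validation, versus
  errors up to 15° for argmax.

Units are called HD when Rayleigh $r \ge 0.4$, $p < 0.01$, and at least 100
spikes — a documented convention (the source taxonomy reports HD counts but
no numeric criterion), configurable through `hdtheta_config()`.

The distributive-hypothesis prediction
$R_{pred}(\theta) = \sum_x \lambda(x) t(x,\theta) / \sum_x t(x,\theta)$
computes the directional tuning a purely spatial cell would display given
the joint position-by-direction occupancy; observed tuning well above the
prediction at the preferred direction rules out a spatial confound.

Condition comparisons (light vs dark, circle vs square) are paired t-tests
per measure (mean direction, CW and CCW mean directions, peak direction,
peak rate) with Bonferroni correction across measures; angular measures are
compared through circular differences tested against zero. Identical
paired samples return $t = 0$, $p = 1$.

## Spatial analyses

Rate maps use 2.5 cm bins ("pixels"); the grid covers the arena and a bin
counts as in-arena when it intersects the arena boundary, so dwell
conservation is exact. Spike counts and dwell are each smoothed with a
mask-aware 3 × 3 boxcar before division. Smoothing is on by default for a
measured reason: at 20-min sessions each pixel holds about one second of
dwell, and the raw-map Skaggs information of a *completely untuned* cell
has a sampling-noise floor near 0.3 bits/spike, with abundant ≥9-pixel
noise fragments above the field threshold — the raw defaults would declare
every cell spatially modulated. `smooth_bins = 1` restores raw maps, on
which the identity $\sum_i \lambda_i t_i = N_{spikes}$ holds exactly.

Spatial information is the Skaggs measure
$I = \sum_i p_i (\lambda_i/\bar\lambda) \log_2 (\lambda_i/\bar\lambda)$
in bits/spike over visited in-arena bins. Selectivity is peak rate over
dwell-weighted mean rate. A place field is a 4-connected (side-sharing)
component of at least nine pixels above 20% of the map peak, with one
additional constraint: the component may occupy at most half of the
in-arena pixels. Taken alone, the 20%-of-peak rule marks nearly the whole
arena for any cell with uniform baseline firing, so a "field" must be a
minority region of elevated firing to count as spatial tuning rather than
baseline activity.

## Autocorrelogram model and theta-cycle skipping

The autocorrelogram counts ordered spike pairs at lags −1000…+1000 ms in
1 ms bins (2001 bins, zero-lag self-pairs excluded; exact pair counting,
verified against an $O(n^2)$ oracle). "Autocorrelation of the ISI
distribution" is read as this all-pairs correlogram rather than an
autocorrelation of successive intervals — only the all-pairs form exhibits
the theta peaks at $1/f$ and $2/f$ that the model describes.

The non-normalized correlogram $y$ at lag $x$ is fitted with

$$y(x) = [a_1\cos(\omega_1 x) + a_2\cos(\omega_2 x)]\,e^{-|x|/\tau_1}
 + b + c_1 e^{-|x|/\tau_2} - c_2 e^{-|x|/\tau_3}$$

by bounded Levenberg–Marquardt least squares (minpack.lm). Units need
care: the $\omega$ bounds $[12\pi, 24\pi]$ and $[6\pi, 12\pi]$ rad/s mean
6–12 Hz and 3–6 Hz, so the cosine arguments take the lag in seconds, while
the decay constants are bounded in ms ($\tau_1 \le 5000$, $\tau_2 \le 100$,
$\tau_3 \le 10$), so the exponentials take the lag in ms. Amplitudes
$a_1, a_2, b, c_1, c_2$ are bounded by $[0, N]$ with $N$ the correlogram
peak. The two damped cosines superpose in phase at even theta cycles and in
antiphase at odd ones, producing the alternating low/high peaks; $(c_1,
\tau_2)$ captures the Poisson ISI exponential, $(c_2, \tau_3)$ the
refractory dip, and $b$ the baseline.

Numerical choices: decay constants are bounded below at 0.1 ms (a zero
decay constant is a division by zero; the printed lower bound of 0 is
interpreted as "arbitrarily fast"); the optimiser restarts from a 5 × 5
grid of frequency initials spanning the $\omega$ boxes with the remaining
initials taken from signal statistics (baseline from the tail mean, centre
excess for $c_1$, first-peak excess for the amplitudes); the best
*converged* start wins, with a non-converged best-residual fit kept only as
a flagged fallback. The procedure is deterministic. Noiseless curves drawn
from the model inside the bounds are recovered to machine precision, and
Poisson-noise correlograms at $N \approx 500$ recover the frequency ratio
to a few percent.

Derived indices:

* **Jump factor** $= a_2/(a_1+a_2)$: the share of the half-frequency
  oscillation in the high peaks; above 0.5 the slow oscillation dominates.
* **Frequency ratio** $= \omega_1/\omega_2$: near 2 when the superposition
  account holds.
* **Theta-skipping index (TS)** $= (P_2 - P_1)/\max(P_1, P_2) \in [-1, 1]$,
  where $P_1, P_2$ are the first and second local maxima after the centre
  peak. The index is positive when alternate cycles are skipped. Peaks are
  measured by default on the *stationary* part of the fitted model — the
  damped cosines plus $b$ — rather than on the full curve: the share of the
  slow ISI exponential at the first peak is a fitting degeneracy (the
  optimiser can trade $b$ against $c_1$ with $\tau_2$ at its bound), and
  including it can flip the sign of a small TS. Full-curve and
  smoothed-raw-counts modes are available.

A unit is *classified* theta-cycle skipping when the fit converged, TS > 0,
the jump factor reaches 0.2, and the oscillation is statistically required
by the data: a nested-model F test against a baseline-plus-exponentials
null, at $\alpha = 10^{-6}$ (a nominal 0.001 Bonferroni-corrected for the
~10³ effective frequency–decay combinations the bounded multi-start fit
scans; without the correction the fit dresses pure count noise in a small
spurious oscillation with nominal p down to 10⁻⁴, while genuine skipping
trains sit below 10⁻⁵⁰). Theta-modulation strength for the broader
taxonomy is the relative depth $a_1/b$ of the fitted theta cosine, banded
at 0.3 (modulated) and 0.1 (weakly modulated), counted only when the same
F test passes — these bands, the 10 Hz fast-firing cut and the HD criterion
are package conventions absent from the source taxonomy, and all live in
`hdtheta_config()`.

## Validation scale

The test suite validates parameter recovery at the study conditions —
20-min sessions at 50 Hz for directional and spatial checks, 600 s trains
at 5 Hz mean rate for the autocorrelogram model, with 5–20 seeds per
property — and the acceptance script fits 20 such trains; a full run of
suite plus script takes a couple of minutes on one core. Known limitations:
the TS magnitude under the default generator is modest (~0.1, versus ~0.33
in strongly skipping recorded cells) because the generator's modulation
depths enter the correlogram quadratically; classification thresholds are
conventions; and the simulator's behavioural realism is limited as noted
above.
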