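# hdtheta

Single-unit analysis of extracellular recordings from freely moving rats
foraging in open arenas, for labs characterising head-direction (HD) and
theta-rhythmic cells in the limbic system. The package builds directional
tuning curves, splits them by clockwise/counter-clockwise head turns,
computes spatial rate maps with Skaggs information and place-field
detection, and — its core — fits an extended damped two-cosine model to
spike-train autocorrelograms to quantify theta-cycle skipping. A
ground-truth session simulator makes every estimator testable end to end.

## The models

**Directional tuning.** Firing rate versus head direction in 72 bins of 5°,
with rate = spikes / dwell per bin; curves are normalized to peak 1 and
aligned to 180° for population averaging. Samples with angular head
velocity ≥ +120°/s (clockwise; the sign convention is fixed so positive =
CW) or ≤ −120°/s (counter-clockwise) define per-category curves whose
preferred-direction offset is the *separation angle*. The
distributive-hypothesis prediction
R(θ) = Σₓ λ(x) t(x, θ) / Σₓ t(x, θ) tests whether apparent directional
tuning is a spatial-occupancy artefact.

**Spatial metrics.** Occupancy-normalized rate maps on 2.5 cm pixels;
Skaggs information I = Σᵢ pᵢ (λᵢ/λ̄) log₂(λᵢ/λ̄) in bits/spike;
selectivity = peak/mean rate; place fields as ≥ 9 side-sharing pixels above
20% of the map peak (and at most half the arena).

**Theta-cycle skipping.** The ±1000 ms, 1 ms-bin autocorrelogram is fitted
with

    y(x) = [a1 cos(ω1 x) + a2 cos(ω2 x)] · exp(−|x|/τ1)
           + b + c1·exp(−|x|/τ2) − c2·exp(−|x|/τ3)

with ω1 ∈ [12π, 24π] rad/s (6–12 Hz), ω2 ∈ [6π, 12π] rad/s (3–6 Hz),
τ1 ≤ 5000 ms, τ2 ≤ 100 ms, τ3 ≤ 10 ms and amplitudes in [0, N] (N the
correlogram peak), by bounded multi-start Levenberg–Marquardt. Derived
indices: the **jump factor** a2/(a1+a2) (contribution of the half-frequency
oscillation to the high peaks), the **frequency ratio** ω1/ω2 (≈ 2 under
the superposition account), and the **theta-skipping index**
TS = (P2 − P1)/max(P1, P2) from the first two post-centre peaks, positive
when alternate theta cycles are skipped.

## Worked example

```r
library(hdtheta)

## a 20-minute foraging session in the 96 cm circular arena
arena  <- arena_spec("circle")
traj   <- simulate_trajectory(arena, duration_s = 1200, seed = 1)
hd     <- head_direction_from_leds(traj)
angvel <- angular_velocity(hd)
docc   <- directional_occupancy(hd)
occ    <- spatial_occupancy(traj)
session_inclusion(occ, docc)$coverage_fraction
#> [1] 0.977            # >= 0.9 and all 72 bins sampled: session accepted

## an HD cell tuned to 90 deg with a 20 deg CW/CCW separation
truth  <- ground_truth("hd", preferred_direction_deg = 90, kappa = 4,
                       peak_rate_hz = 30, baseline_hz = 0.5,
                       cw_ccw_offset_deg = 20)
spikes <- generate_hd_spike_train(traj, truth, seed = 11)
m <- hd_metrics(spikes, hd, angvel, docc)
c(m$preferred_direction_deg, m$peak_rate_hz, m$rayleigh_r,
  m$separation_angle_deg)
#> [1] 90.3  29.8  0.787  19.5
```

The estimated preferred direction (90.3°), peak rate (29.8 Hz) and
separation angle (19.5°) recover the generated 90°, ~30 Hz and 20°; the
Rayleigh vector length 0.787 marks strong directionality. The same unit
carries no spatial signal — 0.063 bits/spike, no place field — so
`classify_unit()` calls it `"hd"`.

```r
## a theta-cycle-skipping cell: 8.67 Hz theta, alternate cycles attenuated
tt  <- ground_truth("theta_skipping", baseline_hz = 5)
st  <- generate_theta_skipping_train(600, tt, seed = 1)
fit <- fit_skipping_model(autocorrelogram(st))
fit
#> Damped two-cosine autocorrelogram fit
#>   f_high 8.67 Hz  f_low 4.38 Hz  (ratio 1.980)
#>   a1 2.77  a2 1.21  b 14.48  c1 0.00  c2 3.72
#>   tau1 5000 ms  tau2 100.0 ms  tau3 10.00 ms
#>   residual norm 166.0  converged TRUE
skipping_indices(fit)
#> jump 0.305, ratio 1.980, TS 0.125
```

The fitted high frequency lands on the generated 8.67 Hz, the frequency
ratio is ~2 as the two-oscillation superposition predicts, the jump factor
0.305 matches its analytic target m2²/(m1²+m2²) ≈ 0.31 for the generator's
modulation depths, and the positive TS reflects the skipped cycles;
`classify_theta_skipping()` returns `TRUE`.

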