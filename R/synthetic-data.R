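#' Arena specification
#'
#' Describes the open-field arena a session was (or is simulated to be)
#' recorded in: a 96 cm diameter circle or a 60 x 60 cm square, the two
#' apparatus used in the pellet-chasing paradigm this package models.
#'
#' @param shape `"circle"` or `"square"`.
#' @param diameter_cm circle diameter in cm (used when `shape = "circle"`).
#' @param side_cm square side length in cm (used when `shape = "square"`).
#' @return an object of class `arena_spec`.
#' @export
arena_spec <- function(shape = c("circle", "square"), diameter_cm = 96,
                       side_cm = 60) {
  shape <- match.arg(shape)
  check_scalar_pos(diameter_cm, "diameter_cm")
  check_scalar_pos(side_cm, "side_cm")
  structure(list(shape = shape, diameter_cm = diameter_cm, side_cm = side_cm),
            class = "arena_spec")
}

## Half-extent of the arena along one axis (arena is centred on the origin)
arena_half_extent <- function(arena) {
  if (arena$shape == "circle") arena$diameter_cm / 2 else arena$side_cm / 2
}

arena_contains <- function(arena, x, y) {
  h <- arena_half_extent(arena)
  if (arena$shape == "circle") (x^2 + y^2) <= h^2
  else (abs(x) <= h) & (abs(y) <= h)
}

#' Ground-truth parameters for a simulated unit
#'
#' Collects every parameter the spike-train generators read, together with the
#' unit's nominal kind, so downstream recovery tests can compare estimates
#' against known truth.
#'
#' @param cell_kind one of `"hd"`, `"place"`, `"theta"`, `"theta_skipping"`,
#'   `"poisson"`.
#' @param preferred_direction_deg preferred head direction (degrees, `[0,360)`).
#' @param kappa von Mises concentration of the directional tuning (>= 0).
#' @param peak_rate_hz tuning peak firing rate above baseline, Hz.
#' @param baseline_hz baseline firing rate, Hz. For the theta kinds this is the
#'   mean rate of the oscillating intensity.
#' @param cw_ccw_offset_deg separation between the clockwise and
#'   counter-clockwise preferred directions (the CW preferred direction is
#'   rotated by `+offset/2`, the CCW one by `-offset/2`).
#' @param field_center_xy place-field centre, cm (length-2).
#' @param field_sigma_cm Gaussian place-field width, cm.
#' @param f_theta_hz theta frequency of the oscillating intensity, Hz.
#' @param depth_theta modulation depth of the theta-frequency cosine (m1).
#' @param depth_skip modulation depth of the half-theta cosine (m2);
#'   `depth_theta + depth_skip <= 1` keeps the intensity non-negative.
#' @param seed integer recorded for provenance.
#' @return an object of class `ground_truth`.
#' @export
ground_truth <- function(cell_kind = c("hd", "place", "theta",
                                       "theta_skipping", "poisson"),
                         preferred_direction_deg = 90, kappa = 4,
                         peak_rate_hz = 30, baseline_hz = 0.5,
                         cw_ccw_offset_deg = 0,
                         field_center_xy = c(0, 0), field_sigma_cm = 8,
                         f_theta_hz = 8.67, depth_theta = 0.6,
                         depth_skip = 0.4, seed = NA_integer_) {
  cell_kind <- match.arg(cell_kind)
  if (kappa < 0) stop_invalid("kappa must be >= 0")
  if (peak_rate_hz < 0 || baseline_hz < 0)
    stop_invalid("firing rates must be >= 0")
  if (depth_theta < 0 || depth_skip < 0)
    stop_invalid("modulation depths must be >= 0")
  if (depth_theta + depth_skip > 1)
    stop_invalid("depth_theta + depth_skip must be <= 1 ",
                 "(intensity would go negative)")
  if (cell_kind %in% c("theta", "theta_skipping", "poisson") &&
      missing(baseline_hz))
    baseline_hz <- 5
  structure(list(cell_kind = cell_kind,
                 preferred_direction_deg = wrap_deg(preferred_direction_deg),
                 kappa = kappa, peak_rate_hz = peak_rate_hz,
                 baseline_hz = baseline_hz,
                 cw_ccw_offset_deg = cw_ccw_offset_deg,
                 field_center_xy = field_center_xy,
                 field_sigma_cm = field_sigma_cm,
                 f_theta_hz = f_theta_hz, depth_theta = depth_theta,
                 depth_skip = depth_skip, seed = seed),
            class = "ground_truth")
}

spike_train <- function(spike_times, session_duration, unit_id = "u1") {
  if (any(is.na(spike_times))) stop_invalid("spike times contain NA")
  if (is.unsorted(spike_times)) stop_invalid("spike times must be sorted")
  if (length(spike_times) &&
      (spike_times[1L] < 0 || spike_times[length(spike_times)] > session_duration))
    stop_invalid("spike times must lie in [0, session_duration]")
  structure(list(unit_id = unit_id, spike_times = as.numeric(spike_times),
                 session_duration = session_duration),
            class = "spike_train")
}

## AR(1)/Ornstein-Uhlenbeck sample path around `mu` with stationary sd `sd`
## and relaxation time `tau_s`, at step `dt`.
ou_path <- function(n, mu, sd, tau_s, dt, x0 = NULL) {
  a <- exp(-dt / tau_s)
  innov_sd <- sd * sqrt(1 - a^2)
  x0 <- if (is.null(x0)) rnorm(1, mu, sd) else x0
  dev <- stats::filter(rnorm(n, 0, innov_sd), a, method = "recursive",
                       init = x0 - mu)
  mu + as.numeric(dev)
}

#' Simulate a pellet-chasing foraging trajectory
#'
#' Generates a smooth, space-filling random walk emulating a rat foraging for
#' scattered food pellets in an open arena: running speed and turning rate are
#' mean-reverting (Ornstein-Uhlenbeck) processes, the path reflects off the
#' walls, and head direction is simulated as its own smooth angular process on
#' top of the body path (rats scan their heads largely independently of their
#' running direction, and the clockwise/counter-clockwise analyses need
#' substantial time at angular head velocities beyond 120 deg/s). Two head
#' LEDs are placed `led_separation_cm` apart along the head axis.
#'
#' A `duration_s` of 0 yields a single sample at t = 0.
#'
#' @param arena an [arena_spec()].
#' @param duration_s session length in seconds (sessions in this paradigm are
#'   typically 20 min = 1200 s).
#' @param sample_rate_hz tracker sampling rate, Hz (default 50).
#' @param seed integer RNG seed; identical inputs give identical trajectories.
#' @param led_separation_cm distance between the two head LEDs, cm.
#' @param speed_mean_cm_s,speed_sd_cm_s,speed_tau_s running-speed process:
#'   mean, stationary sd and relaxation time.
#' @param turn_sd_deg_s,turn_tau_s body-turning-rate process (deg/s, s).
#' @param hd_omega_sd_deg_s,hd_omega_tau_s angular head velocity process
#'   (deg/s, s); the default sd of 160 deg/s puts roughly 40% of samples
#'   beyond the 120 deg/s split threshold, as in fast head-scanning rats.
#' @return an object of class `trajectory` with fields `timestamps`,
#'   `led1_xy`, `led2_xy` (n x 2 matrices, cm; led1 is the front LED),
#'   `arena`, `sample_rate_hz`.
#' @export
simulate_trajectory <- function(arena, duration_s = 1200, sample_rate_hz = 50,
                                seed = 1L, led_separation_cm = 6,
                                speed_mean_cm_s = 20, speed_sd_cm_s = 8,
                                speed_tau_s = 1,
                                turn_sd_deg_s = 60, turn_tau_s = 0.7,
                                hd_omega_sd_deg_s = 160, hd_omega_tau_s = 0.4) {
  if (!inherits(arena, "arena_spec")) stop_invalid("arena must be an arena_spec")
  if (duration_s < 0) stop_invalid("duration_s must be >= 0")
  check_scalar_pos(sample_rate_hz, "sample_rate_hz")
  set.seed(seed)
  dt <- 1 / sample_rate_hz
  n <- as.integer(round(duration_s * sample_rate_hz)) + 1L
  h <- arena_half_extent(arena)

  ## body motion
  speed <- pmax(ou_path(n, speed_mean_cm_s, speed_sd_cm_s, speed_tau_s, dt), 0)
  turn <- ou_path(n, 0, turn_sd_deg_s, turn_tau_s, dt)
  phi <- (runif(1, 0, 360) + cumsum(turn) * dt) * pi / 180
  start <- runif(2, -h / 2, h / 2)
  if (arena$shape == "circle") start <- start * 0.9

  dx <- speed * cos(phi) * dt
  dy <- speed * sin(phi) * dt
  x <- start[1] + cumsum(dx)
  y <- start[2] + cumsum(dy)
  x[1] <- start[1]; y[1] <- start[2]; dx[1] <- 0; dy[1] <- 0

  ## specular wall reflections: at the first out-of-arena sample, reflect the
  ## remaining heading sequence and recompute the path from there
  guard <- 0L
  repeat {
    out <- which(!arena_contains(arena, x, y))
    if (!length(out)) break
    j <- out[1L]
    guard <- guard + 1L
    if (guard > 100000L) stop("trajectory reflection failed to converge")
    px <- if (j > 1L) x[j - 1L] else start[1]
    py <- if (j > 1L) y[j - 1L] else start[2]
    if (arena$shape == "circle") {
      r <- sqrt(px^2 + py^2)
      if (r > 0.999 * h) { px <- px * 0.995 * h / r; py <- py * 0.995 * h / r }
      alpha <- atan2(py, px)
      phi_new <- 2 * alpha + pi - phi[j]
    } else {
      if (abs(px) > 0.999 * h) px <- sign(px) * 0.995 * h
      if (abs(py) > 0.999 * h) py <- sign(py) * 0.995 * h
      xe <- abs(x[j]) > h
      phi_new <- if (xe) pi - phi[j] else -phi[j]
    }
    idx <- j:n
    phi[idx] <- phi[idx] + (phi_new - phi[j])
    dx[idx] <- speed[idx] * cos(phi[idx]) * dt
    dy[idx] <- speed[idx] * sin(phi[idx]) * dt
    x[idx] <- px + cumsum(dx[idx])
    y[idx] <- py + cumsum(dy[idx])
  }

  ## head direction: wrapped integral of an OU angular velocity
  hd_omega <- ou_path(n, 0, hd_omega_sd_deg_s, hd_omega_tau_s, dt)
  theta <- (runif(1, 0, 360) + cumsum(hd_omega) * dt) * pi / 180
  half <- led_separation_cm / 2
  led1 <- cbind(x + half * cos(theta), y + half * sin(theta))
  led2 <- cbind(x - half * cos(theta), y - half * sin(theta))

  structure(list(timestamps = seq(0, by = dt, length.out = n),
                 led1_xy = led1, led2_xy = led2, arena = arena,
                 sample_rate_hz = sample_rate_hz),
            class = "trajectory")
}

#' Midpoint positions of a trajectory
#' @param traj a `trajectory`.
#' @return n x 2 matrix of LED-midpoint coordinates, cm.
#' @export
trajectory_positions <- function(traj) (traj$led1_xy + traj$led2_xy) / 2

trajectory_duration <- function(traj) {
  n <- length(traj$timestamps)
  (n - 1L) / traj$sample_rate_hz
}

## Inhomogeneous Poisson sampling by thinning: homogeneous candidates at
## `lambda_max`, kept with probability lambda(t)/lambda_max.
thin_poisson <- function(lambda_fn, lambda_max, duration_s, seed) {
  set.seed(seed)
  if (lambda_max <= 0 || duration_s <= 0) return(numeric(0))
  n_cand <- rpois(1L, lambda_max * duration_s)
  if (n_cand == 0L) return(numeric(0))
  tc <- sort(runif(n_cand, 0, duration_s))
  u <- runif(n_cand)
  tc[u < lambda_fn(tc) / lambda_max]
}

## lambda lookup on the tracker grid by nearest sample
grid_lambda_fn <- function(timestamps, lambda_values) {
  force(timestamps); force(lambda_values)
  function(t) lambda_values[nearest_index(t, timestamps)]
}

#' Simulate a head-direction cell spike train
#'
#' Inhomogeneous Poisson spikes with von Mises directional intensity
#' `lambda(t) = baseline + peak * exp(kappa * (cos(theta(t) - theta_p(t)) - 1))`
#' where `theta(t)` is the head direction of the trajectory and the preferred
#' direction `theta_p(t)` is offset by `+cw_ccw_offset/2` during clockwise and
#' `-cw_ccw_offset/2` during counter-clockwise head turns.
#'
#' @param traj a [simulate_trajectory()] result.
#' @param truth a [ground_truth()] with `cell_kind = "hd"`.
#' @param seed integer RNG seed.
#' @return a `spike_train`.
#' @export
generate_hd_spike_train <- function(traj, truth, seed = 1L) {
  if (truth$cell_kind != "hd") stop_invalid("truth$cell_kind must be 'hd'")
  hd <- head_direction_from_leds(traj)
  av <- angular_velocity(hd)
  pref <- truth$preferred_direction_deg +
    sign(av$omega_deg_per_s) * truth$cw_ccw_offset_deg / 2
  lam <- truth$baseline_hz + truth$peak_rate_hz *
    exp(truth$kappa * (cos((hd$theta_deg - pref) * pi / 180) - 1))
  dur <- trajectory_duration(traj)
  st <- thin_poisson(grid_lambda_fn(traj$timestamps, lam),
                     truth$baseline_hz + truth$peak_rate_hz, dur, seed)
  spike_train(st, dur, unit_id = "hd")
}

#' Simulate a theta / theta-cycle-skipping spike train
#'
#' Inhomogeneous Poisson spikes whose intensity superposes a theta-frequency
#' and a half-theta-frequency cosine,
#' `lambda(t) = r0 * (1 + m1 cos(2 pi f t) + m2 cos(pi f t))`:
#' the half-frequency term attenuates alternate theta cycles, producing the
#' alternating low/high autocorrelogram peaks characteristic of theta-cycle
#' skipping. `m2 = 0` gives a plain theta-modulated train; `m1 = m2 = 0` a
#' homogeneous Poisson train.
#'
#' @param duration_s session length, s.
#' @param truth a [ground_truth()] whose `baseline_hz` is the mean rate `r0`,
#'   `f_theta_hz` the theta frequency `f`, `depth_theta` = m1 and
#'   `depth_skip` = m2.
#' @param seed integer RNG seed.
#' @return a `spike_train`.
#' @export
generate_theta_skipping_train <- function(duration_s, truth, seed = 1L) {
  if (!truth$cell_kind %in% c("theta", "theta_skipping", "poisson"))
    stop_invalid("truth$cell_kind must be a theta/poisson kind")
  r0 <- truth$baseline_hz; m1 <- truth$depth_theta; m2 <- truth$depth_skip
  f <- truth$f_theta_hz
  if (r0 < 0) stop_invalid("baseline_hz must be >= 0")
  lam <- function(t) pmax(r0 * (1 + m1 * cos(2 * pi * f * t) +
                                  m2 * cos(pi * f * t)), 0)
  st <- thin_poisson(lam, r0 * (1 + m1 + m2), duration_s, seed)
  spike_train(st, duration_s, unit_id = truth$cell_kind)
}

#' Simulate a place cell spike train
#'
#' Inhomogeneous Poisson spikes with Gaussian spatial intensity
#' `lambda(t) = baseline + peak * exp(-|x(t) - c|^2 / (2 sigma^2))` evaluated
#' at the LED midpoint.
#'
#' @param traj a trajectory.
#' @param truth a [ground_truth()] with `cell_kind = "place"`.
#' @param seed integer RNG seed.
#' @return a `spike_train`.
#' @export
generate_place_spike_train <- function(traj, truth, seed = 1L) {
  if (truth$cell_kind != "place") stop_invalid("truth$cell_kind must be 'place'")
  if (truth$field_sigma_cm <= 0) stop_invalid("field_sigma_cm must be > 0")
  pos <- trajectory_positions(traj)
  d2 <- (pos[, 1] - truth$field_center_xy[1])^2 +
    (pos[, 2] - truth$field_center_xy[2])^2
  lam <- truth$baseline_hz +
    truth$peak_rate_hz * exp(-d2 / (2 * truth$field_sigma_cm^2))
  dur <- trajectory_duration(traj)
  st <- thin_poisson(grid_lambda_fn(traj$timestamps, lam),
                     truth$baseline_hz + truth$peak_rate_hz, dur, seed)
  spike_train(st, dur, unit_id = "place")
}
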