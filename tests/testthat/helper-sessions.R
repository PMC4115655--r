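# Shared fixtures, built once per test run. Sessions are generated at reduced
# duration where the check allows it; the full 1200 s reference session is
# shared across files.

fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, fixture_env)) assign(name, build(), fixture_env)
  get(name, fixture_env)
}

ref_session <- function() {
  fixture("ref_session", function() {
    arena <- arena_spec("circle")
    traj <- simulate_trajectory(arena, 1200, 50, seed = 1)
    hd <- head_direction_from_leds(traj)
    list(arena = arena, traj = traj, hd = hd,
         angvel = angular_velocity(hd),
         docc = directional_occupancy(hd),
         occ = spatial_occupancy(traj))
  })
}

ref_hd_train <- function() {
  fixture("ref_hd_train", function() {
    s <- ref_session()
    truth <- ground_truth("hd", preferred_direction_deg = 90, kappa = 4,
                          peak_rate_hz = 30, baseline_hz = 0.5,
                          cw_ccw_offset_deg = 20)
    list(truth = truth,
         spikes = generate_hd_spike_train(s$traj, truth, seed = 11))
  })
}

ref_skipping_fit <- function() {
  fixture("ref_skipping_fit", function() {
    truth <- ground_truth("theta_skipping", baseline_hz = 5)
    spikes <- generate_theta_skipping_train(600, truth, seed = 1)
    acorr <- autocorrelogram(spikes)
    list(truth = truth, spikes = spikes, acorr = acorr,
         fit = fit_skipping_model(acorr))
  })
}

# hand-rolled trajectory with a prescribed head-direction series (for
# tracking-level unit tests that need exact headings)
synthetic_hd_trajectory <- function(theta_deg, sample_rate_hz = 50,
                                    arena = arena_spec("circle")) {
  n <- length(theta_deg)
  th <- theta_deg * pi / 180
  mid <- cbind(rep(0, n), rep(0, n))
  structure(list(timestamps = seq(0, by = 1 / sample_rate_hz,
                                  length.out = n),
                 led1_xy = mid + 3 * cbind(cos(th), sin(th)),
                 led2_xy = mid - 3 * cbind(cos(th), sin(th)),
                 arena = arena, sample_rate_hz = sample_rate_hz),
            class = "trajectory")
}
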