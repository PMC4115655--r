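test_that("arena and ground-truth constructors validate their inputs", {
  expect_s3_class(arena_spec("circle"), "arena_spec")
  expect_error(arena_spec("circle", diameter_cm = -1), "positive")
  expect_error(ground_truth("hd", kappa = -1), "kappa")
  expect_error(ground_truth("hd", peak_rate_hz = -2), "rates")
  expect_error(ground_truth("theta_skipping", depth_theta = 0.7,
                            depth_skip = 0.5), "negative")
})

test_that("trajectories stay inside the arena and handle degenerate duration", {
  s <- ref_session()
  pos <- trajectory_positions(s$traj)
  expect_true(all(sqrt(rowSums(pos^2)) <= 48 + 1e-9))
  expect_equal(length(s$traj$timestamps), 1200 * 50 + 1)

  t0 <- simulate_trajectory(arena_spec("square"), 0, 50, seed = 3)
  expect_equal(length(t0$timestamps), 1L)  # duration 0 -> single sample at t=0

  sq <- simulate_trajectory(arena_spec("square"), 60, 50, seed = 4)
  psq <- trajectory_positions(sq)
  expect_true(all(abs(psq) <= 30 + 1e-9))
  expect_error(simulate_trajectory(arena_spec("circle"), 10, -5),
               "sample_rate")
})

test_that("trajectory generation is seed-deterministic", {
  a <- simulate_trajectory(arena_spec("circle"), 30, 50, seed = 7)
  b <- simulate_trajectory(arena_spec("circle"), 30, 50, seed = 7)
  expect_identical(a, b)
  c <- simulate_trajectory(arena_spec("circle"), 30, 50, seed = 8)
  expect_false(identical(a$led1_xy, c$led1_xy))
})

test_that("long sessions cover space and direction as foraging should", {
  # brute-force occupancy oracle: count distinct visited 2.5 cm bins directly
  s <- ref_session()
  pos <- trajectory_positions(s$traj)
  edges <- seq(-48.75, 48.75, by = 2.5)
  ix <- findInterval(pos[, 1], edges, all.inside = TRUE)
  iy <- findInterval(pos[, 2], edges, all.inside = TRUE)
  visited <- unique(ix + 39 * iy)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  cx <- rep(centers, times = 39); cy <- rep(centers, each = 39)
  in_arena <- sqrt(pmax(abs(cx) - 1.25, 0)^2 + pmax(abs(cy) - 1.25, 0)^2) <= 48
  expect_gte(length(visited) / sum(in_arena), 0.9)
  # all 72 directional bins sampled
  expect_true(all(s$docc$dwell_s > 0))
})

test_that("thinned spike trains match their target intensity", {
  s <- ref_session()
  # HD cell: empirical mean rate within 3 SE of the time-average intensity
  tr <- ref_hd_train()
  hd <- s$hd
  av <- angular_velocity(hd)
  pref <- tr$truth$preferred_direction_deg +
    sign(av$omega_deg_per_s) * tr$truth$cw_ccw_offset_deg / 2
  lam <- tr$truth$baseline_hz + tr$truth$peak_rate_hz *
    exp(tr$truth$kappa * (cos((hd$theta_deg - pref) * pi / 180) - 1))
  expected <- mean(lam)
  n <- length(tr$spikes$spike_times)
  expect_lt(abs(n / 1200 - expected), 3 * sqrt(expected / 1200))

  # zero intensity -> empty train
  z <- ground_truth("hd", peak_rate_hz = 0, baseline_hz = 0)
  expect_length(generate_hd_spike_train(s$traj, z, seed = 2)$spike_times, 0)

  # determinism
  t1 <- generate_theta_skipping_train(60, ground_truth("theta_skipping",
                                                       baseline_hz = 5), 9)
  t2 <- generate_theta_skipping_train(60, ground_truth("theta_skipping",
                                                       baseline_hz = 5), 9)
  expect_identical(t1, t2)

  # bounds
  expect_true(all(t1$spike_times >= 0 & t1$spike_times <= 60))
})

test_that("flat directional tuning yields near-zero Rayleigh vector", {
  s <- ref_session()
  flat <- ground_truth("hd", kappa = 0, peak_rate_hz = 10, baseline_hz = 0)
  st <- generate_hd_spike_train(s$traj, flat, seed = 21)
  idx <- hdtheta:::nearest_index(st$spike_times, s$hd$timestamps)
  r <- rayleigh_statistics(s$hd$theta_deg[idx])$r
  expect_lt(r, 0.05)
})

test_that("hd tuning recovery: empirical peak near the generated direction", {
  # binning oracle: histogram of spike headings / dwell, argmax within 5 deg
  s <- ref_session()
  truth <- ground_truth("hd", preferred_direction_deg = 90, kappa = 4,
                        peak_rate_hz = 30, baseline_hz = 0.5)
  st <- generate_hd_spike_train(s$traj, truth, seed = 31)
  idx <- hdtheta:::nearest_index(st$spike_times, s$hd$timestamps)
  cnt <- tabulate(floor(s$hd$theta_deg[idx] / 5) + 1, nbins = 72)
  rate <- cnt / s$docc$dwell_s
  peak_bin_center <- seq(2.5, 360, by = 5)[which.max(rate)]
  expect_lte(abs(circ_diff_deg(peak_bin_center, 90)), 5)
})

test_that("skipping generator produces alternating autocorrelogram peaks", {
  f <- ref_skipping_fit()
  # analytic peak positions: 1/f = 115 ms and 2/f = 231 ms for f = 8.67 Hz
  sm <- stats::filter(f$acorr$counts, rep(1 / 21, 21))
  pos <- which(f$acorr$lag_ms > 50 & f$acorr$lag_ms < 300)
  y <- as.numeric(sm[pos]); lg <- f$acorr$lag_ms[pos]
  d <- diff(y)
  pk <- lg[which(d[-length(d)] > 0 & d[-1] <= 0) + 1]
  expect_true(any(abs(pk - 1000 / 8.67) < 15))
  expect_true(any(abs(pk - 2000 / 8.67) < 15))
  # the 2/f peak is the higher one (alternate-cycle skipping)
  h1 <- max(y[abs(lg - 115) < 15]); h2 <- max(y[abs(lg - 231) < 15])
  expect_gt(h2, h1)
})

test_that("unmodulated generator yields a flat autocorrelogram", {
  po <- ground_truth("poisson", baseline_hz = 5, depth_theta = 0,
                     depth_skip = 0)
  st <- generate_theta_skipping_train(600, po, seed = 5)
  ac <- autocorrelogram(st)
  # Poisson 99% band around the expected pair count per bin
  side <- ac$counts[abs(ac$lag_ms) >= 1]
  mu <- mean(side)
  band <- stats::qpois(c(0.0005, 0.9995), mu)
  expect_gt(mean(side >= band[1] & side <= band[2]), 0.97)
})

test_that("place cells concentrate firing at the generated field", {
  s <- ref_session()
  truth <- ground_truth("place", field_center_xy = c(10, -5),
                        field_sigma_cm = 8, peak_rate_hz = 20,
                        baseline_hz = 0.5)
  st <- generate_place_spike_train(s$traj, truth, seed = 41)
  rmap <- rate_map(st, s$traj, s$occ)
  fields <- detect_place_fields(rmap)
  expect_gte(length(fields), 1)
  # true centre pixel is a member of a detected field
  ij <- hdtheta:::pos_bin_index(matrix(c(10, -5), 1), s$occ$edges_cm)
  hit <- any(vapply(fields, function(f)
    any(f$member_pixels[, 1] == ij[1] & f$member_pixels[, 2] == ij[2]),
    logical(1)))
  expect_true(hit)
  expect_error(generate_place_spike_train(
    s$traj, ground_truth("place", field_sigma_cm = -1), 1), "sigma")
})

test_that("uniform firing carries no spatial information", {
  s <- ref_session()
  truth <- ground_truth("place", peak_rate_hz = 0, baseline_hz = 5)
  st <- generate_place_spike_train(s$traj, truth, seed = 51)
  rmap <- rate_map(st, s$traj, s$occ)
  expect_lt(spatial_information(rmap, s$occ), 0.05)
})
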