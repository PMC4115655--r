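test_that("tuning curve conserves spikes and matches a histogram oracle", {
  s <- ref_session()
  tr <- ref_hd_train()
  curve <- tuning_curve(tr$spikes, s$hd, s$docc)
  expect_length(curve$rate_hz, 72)
  expect_equal(sum(curve$spike_count), length(tr$spikes$spike_times))
  # brute-force oracle: independent bin count of spike headings
  idx <- hdtheta:::nearest_index(tr$spikes$spike_times, s$hd$timestamps)
  cnt <- tabulate(floor(s$hd$theta_deg[idx] / 5) + 1, nbins = 72)
  expect_equal(curve$spike_count, cnt)
  expect_equal(curve$rate_hz, cnt / s$docc$dwell_s)
  # zero spikes -> all-zero rates
  empty <- spike_train(numeric(0), 1200)
  expect_equal(tuning_curve(empty, s$hd, s$docc)$rate_hz, rep(0, 72))
  # unsampled bin refused
  bad <- s$docc; bad$dwell_s[5] <- 0
  expect_error(tuning_curve(tr$spikes, s$hd, bad), "sampled")
})

test_that("normalization and 180-degree alignment behave as specified", {
  s <- ref_session()
  tr <- ref_hd_train()
  curve <- tuning_curve(tr$spikes, s$hd, s$docc)
  norm <- normalize_and_align(curve)
  expect_equal(max(norm$rate_hz), 1)
  expect_true(all(norm$rate_hz >= 0 & norm$rate_hz <= 1))
  # peak lands in the bin containing 180 (centre 182.5)
  expect_equal(norm$bin_centers_deg[which.max(norm$rate_hz)], 182.5)
  # cyclic shift preserves the multiset of values (oracle: sorted rates)
  expect_equal(sort(norm$rate_hz), sort(curve$rate_hz / max(curve$rate_hz)))
  # already-aligned curve unchanged up to normalization
  again <- normalize_and_align(norm)
  expect_equal(again$rate_hz, norm$rate_hz)
  # all-zero curve refused
  zero <- tuning_curve(spike_train(numeric(0), 1200), s$hd, s$docc)
  expect_error(normalize_and_align(zero), "peak")
})

test_that("CW/CCW split partitions samples and recovers the offset", {
  s <- ref_session()
  tr <- ref_hd_train()
  sp <- split_cw_ccw(tr$spikes, s$hd, s$angvel)
  n <- length(s$hd$theta_deg)
  expect_equal(sp$n_cw + sp$n_ccw + sp$n_excluded, n)
  # generated 20-degree offset recovered within 7.5 degrees
  expect_lt(abs(sp$separation_angle_deg - 20), 7.5)
  # boundary: a sample at exactly +120 deg/s goes to the CW category
  theta <- (seq(360 * 10, by = -2.4, length.out = 200)) %% 360
  ts2 <- seq(0, by = 0.02, length.out = 200)
  hd2 <- structure(list(timestamps = ts2, theta_deg = theta,
                        sample_rate_hz = 50, n_missing = 0L),
                   class = "hd_series")
  av2 <- structure(list(timestamps = ts2,
                        omega_deg_per_s = rep(120, 200)),
                   class = "angvel_series")
  st2 <- spike_train(ts2[100], 7)
  sp2 <- split_cw_ccw(st2, hd2, av2)
  expect_equal(sp$curve_cw$rate_basis, "visits")
  expect_equal(sp2$n_cw, 200L)
  expect_equal(sum(sp2$curve_cw$spike_count), 1L)
  # no fast samples at all: both curves incomplete
  slow <- angular_velocity(head_direction_from_leds(
    synthetic_hd_trajectory(rep(10, 100))), 1)
  hd3 <- head_direction_from_leds(synthetic_hd_trajectory(rep(10, 100)))
  sp3 <- split_cw_ccw(spike_train(1, 2), hd3, slow)
  expect_true(sp3$curve_cw$incomplete && sp3$curve_ccw$incomplete)
  expect_true(is.na(sp3$separation_angle_deg))
})

test_that("rayleigh statistics match closed forms and the Bessel oracle", {
  r1 <- rayleigh_statistics(rep(90, 20))
  expect_equal(r1$r, 1)
  expect_equal(r1$mean_direction_deg, 90)
  # uniform on the 72 bin centres: resultant vanishes
  expect_lt(rayleigh_statistics(seq(2.5, 360, by = 5))$r, 1e-10)
  # von Mises draws: r approaches I1(k)/I0(k), computed by numerical
  # integration (independent of besselI)
  kappa <- 2
  set.seed(42)
  grid <- seq(-pi, pi, length.out = 20001)
  dens <- exp(kappa * cos(grid))
  cdf <- cumsum(dens) / sum(dens)
  draws <- grid[findInterval(runif(10000), cdf) + 1] * 180 / pi
  r_expected <- sum(cos(grid) * dens) / sum(dens)
  expect_lt(abs(rayleigh_statistics(draws)$r - r_expected), 0.02)
  expect_error(rayleigh_statistics(numeric(0)), "empty")
})

test_that("preferred direction recovery holds across seeds and kappas", {
  arena <- arena_spec("circle")
  for (s in 1:6) {
    traj <- simulate_trajectory(arena, 600, 50, seed = 100 + s)
    hd <- head_direction_from_leds(traj)
    docc <- directional_occupancy(hd)
    kappa <- if (s %% 2 == 0) 2 else 4
    truth <- ground_truth("hd", preferred_direction_deg = 37 * s,
                          kappa = kappa, peak_rate_hz = 25,
                          baseline_hz = 0.5)
    st <- generate_hd_spike_train(traj, truth, seed = 300 + s)
    curve <- tuning_curve(st, hd, docc)
    expect_lt(abs(circ_diff_deg(preferred_direction(curve), 37 * s)), 5)
  }
})

test_that("distributive prediction explains place cells but not HD cells", {
  s <- ref_session()
  jocc <- joint_occupancy(s$traj, s$hd)
  # spatially uniform rate map -> constant prediction
  rflat <- rate_map(spike_train(numeric(0), 1200), s$traj, s$occ)
  rflat$rate_hz[] <- 3.5
  pred <- distributive_predicted_tuning(rflat, jocc)
  expect_equal(pred$rate_hz[!is.na(pred$rate_hz)],
               rep(3.5, sum(!is.na(pred$rate_hz))))
  # place cell: apparent directional tuning is an occupancy artefact the
  # prediction reproduces (peak bins agree within 2 bins)
  pt <- ground_truth("place", field_center_xy = c(15, 8), field_sigma_cm = 10,
                     peak_rate_hz = 20, baseline_hz = 0.5)
  ps <- generate_place_spike_train(s$traj, pt, seed = 61)
  rmap <- rate_map(ps, s$traj, s$occ)
  predp <- distributive_predicted_tuning(rmap, jocc)
  obs <- tuning_curve(ps, s$hd, s$docc)
  expect_gt(cor(predp$rate_hz, obs$rate_hz, use = "complete.obs"), 0.5)
  # true HD cell: observed peak exceeds the prediction at the preferred bin
  tr <- ref_hd_train()
  rhd <- rate_map(tr$spikes, s$traj, s$occ)
  predh <- distributive_predicted_tuning(rhd, jocc)
  obsh <- tuning_curve(tr$spikes, s$hd, s$docc)
  pk <- which.max(obsh$rate_hz)
  expect_gt(obsh$rate_hz[pk], 2 * predh$rate_hz[pk])
})

test_that("paired condition comparison handles identity and a 3-pair oracle", {
  a <- data.frame(unit_id = c("a", "b", "c"),
                  mean_direction_deg = c(10, 200, 355),
                  peak_rate_hz = c(12, 30, 4))
  cmpA <- compare_conditions(a, a, measures = c("mean_direction_deg",
                                                "peak_rate_hz"))
  expect_equal(cmpA$t, c(0, 0))
  expect_equal(cmpA$p, c(1, 1))
  expect_false(any(cmpA$significant))
  # textbook paired t on 3 pairs: d = (1, 2, 3), t = mean/ (sd/sqrt(3))
  b <- a
  b$peak_rate_hz <- a$peak_rate_hz - c(1, 2, 3)
  cmpB <- compare_conditions(a, b, measures = "peak_rate_hz")
  d <- c(1, 2, 3)
  t_oracle <- mean(d) / (sd(d) / sqrt(3))
  expect_equal(cmpB$t, t_oracle, tolerance = 1e-12)
  expect_equal(cmpB$df, 2)
  # angular wrap: 355 vs 5 differ by -10, not 350
  cshift <- a
  cshift$mean_direction_deg <- (a$mean_direction_deg + 10) %% 360
  cmpC <- compare_conditions(a, cshift, measures = "mean_direction_deg")
  expect_equal(abs(cmpC$t), Inf)  # constant -10 difference
  # mismatched unit sets refused
  expect_error(compare_conditions(a, a[1:2, ]), "units")
})
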