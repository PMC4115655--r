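#' Head direction from the two head LEDs
#'
#' The head direction at each tracker sample is the planar angle of the vector
#' from the back LED to the front LED, with 0 degrees along +x and angles
#' increasing counter-clockwise, wrapped to `[0, 360)`. Samples where the LEDs
#' coincide are returned as `NA` and flagged.
#'
#' @param traj a `trajectory`.
#' @return an object of class `hd_series`: `timestamps`, `theta_deg`,
#'   `sample_rate_hz`, `n_missing`.
#' @export
head_direction_from_leds <- function(traj) {
  d <- traj$led1_xy - traj$led2_xy
  bad <- d[, 1] == 0 & d[, 2] == 0
  if (all(bad)) stop_invalid("all LED pairs coincide; no head direction")
  theta <- wrap_deg(atan2(d[, 2], d[, 1]) * 180 / pi)
  theta[bad] <- NA_real_
  structure(list(timestamps = traj$timestamps, theta_deg = theta,
                 sample_rate_hz = traj$sample_rate_hz,
                 n_missing = sum(bad)),
            class = "hd_series")
}

## unwrap a degree series so consecutive steps are in (-180, 180]
unwrap_deg <- function(theta_deg) {
  if (length(theta_deg) < 2L) return(theta_deg)
  theta_deg[1L] + c(0, cumsum(circ_diff_deg(theta_deg[-1L],
                                            theta_deg[-length(theta_deg)])))
}

#' Angular head velocity
#'
#' Central finite difference of the unwrapped head-direction series with an
#' optional boxcar smoother. Sign convention: positive values are CLOCKWISE
#' head turns, so the +120 deg/s split threshold selects clockwise movement.
#' (Screen/mathematical convention has angles growing counter-clockwise; the
#' sign is flipped here so that convention mismatch cannot silently invert
#' the CW/CCW split.)
#'
#' @param hd an `hd_series`.
#' @param smooth_window_samples boxcar width in samples (1 = no smoothing;
#'   default 5).
#' @return an object of class `angvel_series`: `timestamps`,
#'   `omega_deg_per_s` (positive = clockwise).
#' @export
angular_velocity <- function(hd, smooth_window_samples = 5L) {
  if (smooth_window_samples < 1L) stop_invalid("smooth window must be >= 1")
  n <- length(hd$theta_deg)
  if (n < 2L) stop_invalid("need at least 2 samples")
  u <- unwrap_deg(hd$theta_deg)
  dt <- 1 / hd$sample_rate_hz
  ccw <- c(u[2L] - u[1L],
           (u[seq(3L, length.out = n - 2L)] - u[seq_len(n - 2L)]) / 2,
           u[n] - u[n - 1L]) / dt
  omega <- -ccw  # positive = CW
  if (smooth_window_samples > 1L) {
    sm <- as.numeric(stats::filter(omega,
                                   rep(1 / smooth_window_samples,
                                       smooth_window_samples)))
    omega <- ifelse(is.na(sm), omega, sm)
  }
  structure(list(timestamps = hd$timestamps, omega_deg_per_s = omega),
            class = "angvel_series")
}

dir_bin_index <- function(theta_deg, bin_deg) {
  pmin(floor(wrap_deg(theta_deg) / bin_deg) + 1L, 360 / bin_deg)
}

#' Directional occupancy
#'
#' Dwell time and visit counts per head-direction bin (default 72 bins of
#' 5 degrees). A visit is an entry of the heading into a bin (the first sample
#' always starts a visit).
#'
#' @param hd an `hd_series`.
#' @param bin_deg bin width in degrees; must divide 360.
#' @return an object of class `directional_occupancy`: `bin_edges_deg`,
#'   `bin_centers_deg`, `dwell_s`, `visits`.
#' @export
directional_occupancy <- function(hd, bin_deg = 5) {
  if (bin_deg <= 0 || 360 %% bin_deg != 0)
    stop_invalid("bin_deg must divide 360")
  nb <- as.integer(360 / bin_deg)
  ok <- !is.na(hd$theta_deg)
  b <- dir_bin_index(hd$theta_deg[ok], bin_deg)
  dwell <- tabulate(b, nbins = nb) / hd$sample_rate_hz
  entries <- b[c(TRUE, diff(b) != 0L)]
  visits <- tabulate(entries, nbins = nb)
  structure(list(bin_edges_deg = seq(0, 360, by = bin_deg),
                 bin_centers_deg = seq(bin_deg / 2, 360, by = bin_deg),
                 dwell_s = dwell, visits = visits, bin_deg = bin_deg),
            class = "directional_occupancy")
}

## Square grid covering the arena, centred on the origin. A bin is in-arena
## ("mask") when it intersects the arena, so all tracked dwell falls on
## in-arena bins and dwell conservation is exact.
spatial_grid <- function(arena, bin_cm) {
  h <- arena_half_extent(arena)
  nb <- as.integer(ceiling(2 * h / bin_cm))
  edges <- seq(-nb * bin_cm / 2, nb * bin_cm / 2, by = bin_cm)
  centers <- (edges[-1L] + edges[-length(edges)]) / 2
  if (arena$shape == "circle") {
    cx <- matrix(centers, nb, nb)
    cy <- matrix(centers, nb, nb, byrow = TRUE)
    ddx <- pmax(abs(cx) - bin_cm / 2, 0)
    ddy <- pmax(abs(cy) - bin_cm / 2, 0)
    mask <- sqrt(ddx^2 + ddy^2) <= h
  } else {
    mask <- matrix(TRUE, nb, nb)
  }
  list(n = nb, edges = edges, centers = centers, mask = mask)
}

pos_bin_index <- function(xy, edges) {
  n <- length(edges) - 1L
  i <- findInterval(xy[, 1], edges, rightmost.closed = TRUE, all.inside = TRUE)
  j <- findInterval(xy[, 2], edges, rightmost.closed = TRUE, all.inside = TRUE)
  cbind(pmin(pmax(i, 1L), n), pmin(pmax(j, 1L), n))
}

#' Spatial occupancy map
#'
#' Dwell time per square spatial bin, accumulated at the LED-midpoint
#' position. Bins intersecting the arena form the in-arena mask.
#'
#' @param traj a `trajectory`.
#' @param bin_cm bin ("pixel") size in cm, default 2.5.
#' @return an object of class `occupancy_map`: `dwell_s` (matrix, rows = x
#'   bins), `mask`, `bin_cm`, `edges_cm`, `sample_rate_hz`, `duration_s`.
#' @export
spatial_occupancy <- function(traj, bin_cm = 2.5) {
  check_scalar_pos(bin_cm, "bin_cm")
  g <- spatial_grid(traj$arena, bin_cm)
  pos <- trajectory_positions(traj)
  ij <- pos_bin_index(pos, g$edges)
  dwell <- matrix(0, g$n, g$n)
  cnt <- table(factor(ij[, 1], levels = seq_len(g$n)),
               factor(ij[, 2], levels = seq_len(g$n)))
  dwell[] <- as.numeric(cnt) / traj$sample_rate_hz
  structure(list(dwell_s = dwell, mask = g$mask, bin_cm = bin_cm,
                 edges_cm = g$edges, sample_rate_hz = traj$sample_rate_hz,
                 duration_s = trajectory_duration(traj)),
            class = "occupancy_map")
}

#' Session inclusion decision
#'
#' A session is accepted for analysis only when the animal explored at least
#' 90% of the open field and every head-direction bin was sampled, the two
#' inclusion rules this analysis inherits from the recording protocol.
#'
#' @param occ an `occupancy_map`.
#' @param docc a `directional_occupancy`.
#' @param coverage_threshold minimum fraction of in-arena bins visited.
#' @return a list: `pass`, `spatial_ok`, `directional_ok`,
#'   `coverage_fraction`.
#' @export
session_inclusion <- function(occ, docc, coverage_threshold = 0.9) {
  visited <- occ$dwell_s > 0 & occ$mask
  coverage <- sum(visited) / sum(occ$mask)
  spatial_ok <- coverage >= coverage_threshold
  directional_ok <- all(docc$dwell_s > 0)
  list(pass = spatial_ok && directional_ok, spatial_ok = spatial_ok,
       directional_ok = directional_ok, coverage_fraction = coverage)
}
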