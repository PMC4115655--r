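## mask-aware boxcar: mean over the k x k neighbourhood restricted to
## in-mask cells (kernel renormalized at edges)
boxcar2d <- function(m, mask, k) {
  if (k <= 1L) return(m)
  w <- (k - 1L) %/% 2L
  num <- matrix(0, nrow(m), ncol(m))
  den <- matrix(0, nrow(m), ncol(m))
  mm <- ifelse(mask, m, 0)
  mk <- mask * 1
  shift <- function(x, di, dj) {
    out <- matrix(0, nrow(x), ncol(x))
    si <- seq_len(nrow(x)); sj <- seq_len(ncol(x))
    ti <- si + di; tj <- sj + dj
    ok_i <- ti >= 1 & ti <= nrow(x); ok_j <- tj >= 1 & tj <= ncol(x)
    out[ti[ok_i], tj[ok_j]] <- x[si[ok_i], sj[ok_j]]
    out
  }
  for (di in -w:w) for (dj in -w:w) {
    num <- num + shift(mm, di, dj)
    den <- den + shift(mk, di, dj)
  }
  ifelse(mask & den > 0, num / den, m)
}

#' Firing rate map
#'
#' Per-bin firing rate (spikes / dwell) on the session occupancy grid; bins
#' without dwell are `NA`. By default spike counts and dwell are each
#' smoothed with a mask-aware 3 x 3 boxcar before division, the standard
#' stabilisation for maps whose per-bin dwell is of order one second — on a
#' raw map the per-bin rate noise alone (~40% CV at typical dwell) produces
#' spurious spatial structure in every untuned cell. Set `smooth_bins = 1`
#' for a raw map (on which the spikes = sum(rate * dwell) identity holds
#' exactly).
#'
#' @param spikes a `spike_train`.
#' @param traj the session `trajectory`.
#' @param occ the session `occupancy_map` (same binning).
#' @param smooth_bins odd boxcar width in bins (1 = no smoothing; default 3).
#' @return an object of class `rate_map`: `rate_hz`, `spike_count`, `mask`,
#'   `bin_cm`, `peak_rate_hz`, `mean_rate_hz` (dwell-weighted mean over
#'   visited in-arena bins).
#' @export
rate_map <- function(spikes, traj, occ, smooth_bins = 3L) {
  if (occ$duration_s <= 0) stop_invalid("zero-duration session")
  if (smooth_bins < 1L || smooth_bins %% 2L == 0L)
    stop_invalid("smooth_bins must be odd and >= 1")
  n <- nrow(occ$dwell_s)
  idx <- spike_sample_index(spikes, traj$timestamps)
  pos <- trajectory_positions(traj)[idx, , drop = FALSE]
  ij <- pos_bin_index(pos, occ$edges_cm)
  count <- matrix(tabulate((ij[, 2] - 1L) * n + ij[, 1], nbins = n * n), n, n)
  cs <- boxcar2d(count, occ$mask, smooth_bins)
  ds <- boxcar2d(occ$dwell_s, occ$mask, smooth_bins)
  rate <- ifelse(occ$dwell_s > 0 & ds > 0, cs / ds, NA_real_)
  visited <- occ$dwell_s > 0 & occ$mask
  w <- occ$dwell_s[visited]
  mean_rate <- if (sum(w) > 0) sum(rate[visited] * w) / sum(w) else 0
  structure(list(rate_hz = rate, spike_count = count, mask = occ$mask,
                 bin_cm = occ$bin_cm,
                 peak_rate_hz = if (any(visited)) max(rate[visited]) else 0,
                 mean_rate_hz = mean_rate),
            class = "rate_map")
}

#' Spatial information content (bits per spike)
#'
#' Skaggs information measure
#' `I = sum_i p_i (lambda_i / lambda_bar) log2(lambda_i / lambda_bar)` with
#' occupancy probabilities `p_i = t_i / sum t` and mean rate
#' `lambda_bar = sum p_i lambda_i`, over visited in-arena bins; zero-rate
#' bins contribute 0.
#'
#' @param rmap a `rate_map`.
#' @param occ the matching `occupancy_map`.
#' @return spatial information in bits per spike.
#' @export
spatial_information <- function(rmap, occ) {
  visited <- occ$dwell_s > 0 & occ$mask
  p <- occ$dwell_s[visited] / sum(occ$dwell_s[visited])
  lam <- rmap$rate_hz[visited]
  lbar <- sum(p * lam)
  if (lbar <= 0) stop_invalid("spatial information undefined: mean rate is 0")
  rel <- lam / lbar
  pos <- rel > 0
  sum(p[pos] * rel[pos] * log2(rel[pos]))
}

## 4-connected component labelling of a logical matrix (flood fill)
label_components4 <- function(m) {
  lab <- matrix(0L, nrow(m), ncol(m))
  cur <- 0L
  for (s in which(m)) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      q <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (lab[q] != 0L || !m[q]) next
      lab[q] <- cur
      i <- (q - 1L) %% nrow(m) + 1L
      j <- (q - 1L) %/% nrow(m) + 1L
      if (i > 1L) stack <- c(stack, q - 1L)
      if (i < nrow(m)) stack <- c(stack, q + 1L)
      if (j > 1L) stack <- c(stack, q - nrow(m))
      if (j < ncol(m)) stack <- c(stack, q + nrow(m))
    }
  }
  lab
}

#' Detect place fields
#'
#' A place field is a set of at least nine side-sharing ("4-connected")
#' pixels whose firing rate exceeds 20% of the map peak; field size is
#' reported in pixels. A component is additionally required to occupy at
#' most `max_arena_fraction` of the in-arena pixels: taken alone, the
#' 20%-of-peak rule marks nearly the whole arena for any cell with uniform
#' baseline firing (most pixels of a flat noisy map exceed a fifth of its
#' peak), so a "field" must be a minority region of elevated firing to count
#' as spatial tuning rather than baseline activity.
#'
#' @param rmap a `rate_map`.
#' @param threshold_frac fraction of the peak rate defining field membership,
#'   default 0.2.
#' @param min_pixels minimum component size, default 9.
#' @param max_arena_fraction maximum field size as a fraction of in-arena
#'   pixels, default 0.5.
#' @return a list of `place_field` objects (`member_pixels` two-column index
#'   matrix, `size_pixels`, `peak_pixel`, `threshold_rate_hz`), empty when no
#'   field qualifies.
#' @export
detect_place_fields <- function(rmap, threshold_frac = 0.2, min_pixels = 9L,
                                max_arena_fraction = 0.5) {
  if (!any(!is.na(rmap$rate_hz) & rmap$mask))
    stop_invalid("rate map has no visited bin")
  if (rmap$peak_rate_hz <= 0) return(list())
  thr <- threshold_frac * rmap$peak_rate_hz
  above <- !is.na(rmap$rate_hz) & rmap$mask & rmap$rate_hz > thr
  lab <- label_components4(above)
  max_px <- max_arena_fraction * sum(rmap$mask)
  out <- list()
  for (k in seq_len(max(lab))) {
    px <- which(lab == k, arr.ind = TRUE)
    if (nrow(px) < min_pixels || nrow(px) > max_px) next
    rates <- rmap$rate_hz[lab == k]
    out[[length(out) + 1L]] <-
      structure(list(member_pixels = px, size_pixels = nrow(px),
                     peak_pixel = px[which.max(rates), ],
                     threshold_rate_hz = thr),
                class = "place_field")
  }
  out
}

#' Spatial selectivity
#'
#' Ratio of the maximal to the mean firing rate over the apparatus (the
#' "maximal signal to noise" ratio); 1 for a spatially uniform map.
#'
#' @param rmap a `rate_map`.
#' @return selectivity ratio (>= 1 whenever the mean rate is positive).
#' @export
selectivity <- function(rmap) {
  if (rmap$mean_rate_hz <= 0)
    stop_invalid("selectivity undefined: mean rate is 0")
  rmap$peak_rate_hz / rmap$mean_rate_hz
}

#' Average firing frequency
#'
#' Total number of spikes divided by the total recording time.
#'
#' @param spikes a `spike_train`.
#' @param duration_s recording duration, s (defaults to the train's own
#'   session duration).
#' @return mean rate in Hz.
#' @export
average_frequency <- function(spikes, duration_s = spikes$session_duration) {
  if (duration_s <= 0) stop_invalid("duration must be > 0")
  length(spikes$spike_times) / duration_s
}

#' Spatial metrics summary for one unit
#'
#' @param spikes a `spike_train`.
#' @param traj the session `trajectory`.
#' @param occ the session `occupancy_map`.
#' @return an object of class `spatial_metrics`: `information_bits_per_spike`
#'   (`NA` when the unit never fired), `selectivity`, `average_rate_hz`,
#'   `fields`, `rate_map`.
#' @export
spatial_metrics <- function(spikes, traj, occ) {
  rmap <- rate_map(spikes, traj, occ)
  fired <- rmap$mean_rate_hz > 0
  structure(list(information_bits_per_spike =
                   if (fired) spatial_information(rmap, occ) else NA_real_,
                 selectivity = if (fired) selectivity(rmap) else NA_real_,
                 average_rate_hz = average_frequency(spikes),
                 fields = if (fired) detect_place_fields(rmap) else list(),
                 rate_map = rmap),
            class = "spatial_metrics")
}
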