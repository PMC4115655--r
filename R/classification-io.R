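#' Analysis configuration
#'
#' Bundles every tunable threshold and bin size, with documented defaults.
#' The HD criterion (Rayleigh r, p, spike count), the theta-modulation bands
#' and the fast-firing cut are conventions of this package: the source
#' taxonomy reports the categories but never their numeric rules.
#'
#' @param ... named overrides of the defaults.
#' @return a named list of class `hdtheta_config`.
#' @export
hdtheta_config <- function(...) {
  cfg <- list(dir_bin_deg = 5, spatial_bin_cm = 2.5,
              angvel_threshold_deg_s = 120,
              rayleigh_r_min = 0.4, rayleigh_p_max = 0.01, hd_min_spikes = 100,
              jump_factor_min = 0.2,
              theta_depth_modulated = 0.3, theta_depth_weak = 0.1,
              osc_alpha = 1e-6,
              fast_firing_hz = 10,
              spatial_info_min = 0.5, coverage_threshold = 0.9,
              match_max_distance = 1.0)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop_invalid("unknown config keys: ",
                                paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  num <- unlist(cfg)
  if (any(!is.finite(num) | num <= 0))
    stop_invalid("all config values must be positive and finite")
  structure(cfg, class = "hdtheta_config")
}

#' Assign a unit to a functional category
#'
#' Deterministic precedence over the taxonomy used for thalamic single
#' units: head-direction > theta-cycle skipping > spatially tuned >
#' theta modulated > fast firing > weakly theta modulated > unidentified
#' low firing. Thresholds come from [hdtheta_config()].
#'
#' @param hd an `hd_metrics` (or `NULL` to refuse).
#' @param spat a `spatial_metrics`.
#' @param skip a list with elements `fit` (`skipping_fit`), `acorr`
#'   (`autocorrelogram`) and optionally `indices`; or `NULL` for units with
#'   too few spikes to autocorrelate (treated as not theta modulated).
#' @param avg_rate_hz mean firing rate over the session.
#' @param config an [hdtheta_config()].
#' @return the category as a length-1 character vector.
#' @export
classify_unit <- function(hd, spat, skip, avg_rate_hz,
                          config = hdtheta_config()) {
  if (is.null(hd)) stop_invalid("classification refused: missing hd metrics")
  if (is.null(spat)) stop_invalid("classification refused: missing spatial metrics")
  if (is.null(avg_rate_hz)) stop_invalid("classification refused: missing avg_rate_hz")

  is_hd <- hd$rayleigh_r >= config$rayleigh_r_min &&
    hd$rayleigh_p < config$rayleigh_p_max &&
    hd$n_spikes >= config$hd_min_spikes
  if (is_hd) return("hd")

  depth <- 0
  if (!is.null(skip)) {
    if (is.null(skip$fit) || is.null(skip$acorr))
      stop_invalid("classification refused: skip must carry fit and acorr")
    if (classify_theta_skipping(skip$fit, skip$acorr, skip$indices,
                                jump_threshold = config$jump_factor_min,
                                osc_alpha = config$osc_alpha))
      return("theta_skipping")
    ## modulation depth only counts when the oscillation is statistically
    ## required; noise fits on sparse autocorrelograms give large a1/b
    if (isTRUE(skip$fit$converged) &&
        oscillation_f_test(skip$fit, skip$acorr)$p < config$osc_alpha)
      depth <- theta_modulation_depth(skip$fit)
  }
  spatially_tuned <- length(spat$fields) > 0 &&
    !is.na(spat$information_bits_per_spike) &&
    spat$information_bits_per_spike >= config$spatial_info_min
  if (spatially_tuned) return("spatially_tuned")
  if (depth >= config$theta_depth_modulated) return("theta_modulated")
  if (avg_rate_hz > config$fast_firing_hz) return("fast_firing")
  if (depth >= config$theta_depth_weak) return("weakly_theta_modulated")
  "unidentified_low_firing"
}

#' Category percentages from a population census
#'
#' Recomputes per-category percentages as `100 * count / n_total`, rounded
#' to one decimal, the arithmetic behind published unit-census tables.
#'
#' @param counts named integer vector of per-category unit counts.
#' @param n_total total number of units the percentages refer to
#'   (default `sum(counts)`).
#' @return a data frame: category, count, percent.
#' @export
category_percentages <- function(counts, n_total = sum(counts)) {
  if (any(counts < 0) || n_total <= 0) stop_invalid("counts must be >= 0")
  data.frame(category = names(counts), count = as.integer(counts),
             percent = round(100 * as.numeric(counts) / n_total, 1),
             row.names = NULL)
}

#' Match units across recording days by waveform statistics
#'
#' Greedy one-to-one nearest-neighbour matching on z-scored spike amplitude,
#' height and duration, with a maximum normalized distance; units farther
#' than that from every remaining candidate stay unmatched.
#'
#' @param day_a,day_b data frames with columns `amplitude`, `height`,
#'   `duration` (one row per unit).
#' @param max_distance maximum z-space Euclidean distance for a match.
#' @return a list: `matches` (data frame a, b, distance), `unmatched_a`,
#'   `unmatched_b` (row indices).
#' @export
match_units_across_days <- function(day_a, day_b, max_distance = 1.0) {
  cols <- c("amplitude", "height", "duration")
  if (!all(cols %in% names(day_a)) || !all(cols %in% names(day_b)))
    stop_invalid("waveform tables need amplitude, height, duration")
  if (nrow(day_a) == 0L || nrow(day_b) == 0L)
    stop_invalid("both unit lists must be non-empty")
  z <- scale(rbind(as.matrix(day_a[cols]), as.matrix(day_b[cols])))
  z[is.nan(z)] <- 0  # zero-variance feature
  dd <- as.matrix(stats::dist(z))
  d <- dd[seq_len(nrow(day_a)),
          nrow(day_a) + seq_len(nrow(day_b)), drop = FALSE]
  matches <- data.frame(a = integer(0), b = integer(0), distance = numeric(0))
  free_a <- rep(TRUE, nrow(d)); free_b <- rep(TRUE, ncol(d))
  while (any(free_a) && any(free_b)) {
    sub <- d
    sub[!free_a, ] <- Inf; sub[, !free_b] <- Inf
    m <- which.min(sub)
    if (!is.finite(sub[m]) || sub[m] > max_distance) break
    i <- (m - 1L) %% nrow(d) + 1L
    j <- (m - 1L) %/% nrow(d) + 1L
    matches <- rbind(matches, data.frame(a = i, b = j, distance = d[i, j]))
    free_a[i] <- FALSE; free_b[j] <- FALSE
  }
  list(matches = matches, unmatched_a = which(free_a),
       unmatched_b = which(free_b))
}

## ---- session file formats -------------------------------------------------
## tracking: CSV `t,x1,y1,x2,y2` (seconds, cm); spikes: CSV `unit_id,t`;
## config sidecar: `key=value` lines.

fmt_num <- function(x) sprintf("%.10g", x)

#' Write a trajectory to the delimited tracking format
#' @param traj a `trajectory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tracking <- function(traj, path) {
  df <- data.frame(t = fmt_num(traj$timestamps),
                   x1 = fmt_num(traj$led1_xy[, 1]), y1 = fmt_num(traj$led1_xy[, 2]),
                   x2 = fmt_num(traj$led2_xy[, 1]), y2 = fmt_num(traj$led2_xy[, 2]))
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read the delimited tracking format
#'
#' @param path tracking file written by [write_tracking()].
#' @param arena the session [arena_spec()].
#' @param sample_rate_hz tracker rate; inferred from timestamps when `NULL`.
#' @return a `trajectory`.
#' @export
read_tracking <- function(path, arena, sample_rate_hz = NULL) {
  df <- utils::read.csv(path)
  need <- c("t", "x1", "y1", "x2", "y2")
  if (!all(need %in% names(df)))
    stop_invalid("tracking file missing columns: ",
                 paste(setdiff(need, names(df)), collapse = ", "))
  bad <- which(!stats::complete.cases(df[need]))
  if (length(bad))
    stop_invalid("non-numeric/missing tracking values at line ", bad[1L] + 1L)
  nm <- which(diff(df$t) <= 0)
  if (length(nm))
    stop_invalid("timestamps not strictly increasing at line ", nm[1L] + 2L)
  if (is.null(sample_rate_hz))
    sample_rate_hz <- 1 / stats::median(diff(df$t))
  structure(list(timestamps = df$t,
                 led1_xy = cbind(df$x1, df$y1), led2_xy = cbind(df$x2, df$y2),
                 arena = arena, sample_rate_hz = sample_rate_hz),
            class = "trajectory")
}

#' Write spike trains to the delimited spike format
#' @param trains a list of `spike_train` objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_spikes <- function(trains, path) {
  rows <- lapply(trains, function(s)
    data.frame(unit_id = s$unit_id, t = fmt_num(s$spike_times)))
  utils::write.table(do.call(rbind, rows), path, sep = ",", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read the delimited spike format
#'
#' Spikes beyond the tracked session duration draw a warning and are
#' truncated (the documented policy for trains that outrun the tracking).
#'
#' @param path spike file written by [write_spikes()].
#' @param session_duration_s session length the spikes belong to.
#' @return a named list of `spike_train` objects, one per unit.
#' @export
read_spikes <- function(path, session_duration_s) {
  df <- utils::read.csv(path, colClasses = c("character", "numeric"))
  if (!all(c("unit_id", "t") %in% names(df)))
    stop_invalid("spike file must have columns unit_id,t")
  neg <- which(df$t < 0 | is.na(df$t))
  if (length(neg))
    stop_invalid("invalid spike time at line ", neg[1L] + 1L)
  out <- list()
  for (u in unique(df$unit_id)) {
    tt <- df$t[df$unit_id == u]
    if (is.unsorted(tt))
      stop_invalid("spike times for unit ", u, " not sorted ascending")
    if (any(tt > session_duration_s)) {
      warning("unit ", u, ": ", sum(tt > session_duration_s),
              " spike(s) beyond session duration truncated", call. = FALSE)
      tt <- tt[tt <= session_duration_s]
    }
    out[[u]] <- spike_train(tt, session_duration_s, unit_id = u)
  }
  out
}

#' Write a session config sidecar (`key=value` text)
#' @param config a named list (e.g. [hdtheta_config()], arena fields, seed).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  keys <- names(config)
  vals <- vapply(config, function(v)
    if (is.numeric(v)) paste(fmt_num(v), collapse = ",")
    else paste(as.character(v), collapse = ","), "")
  writeLines(paste0(keys, "=", vals), path)
  invisible(path)
}

#' Read a `key=value` config sidecar
#' @param path file written by [write_config()].
#' @return a named list of character values (coerce as needed).
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  eq <- regexpr("=", lines, fixed = TRUE)
  if (any(eq < 0)) stop_invalid("malformed config line: ",
                                lines[which(eq < 0)[1L]])
  stats::setNames(as.list(substring(lines, eq + 1L)),
                  substring(lines, 1L, eq - 1L))
}

#' Write a per-unit results table as delimited text
#' @param results a data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
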