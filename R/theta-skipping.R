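#' Inter-spike interval histogram
#'
#' Histogram of successive inter-spike intervals, plus the fraction of
#' intervals shorter than 2 ms: well-isolated units must show a clean
#' refractory period (> 2 ms), so a non-negligible sub-2 ms fraction flags a
#' contaminated cluster.
#'
#' @param spikes a `spike_train` with at least 2 spikes.
#' @param bin_ms histogram bin width, ms.
#' @param refractory_ms refractory boundary, default 2 ms.
#' @return an object of class `isi_histogram`: `bin_edges_ms`, `counts`,
#'   `refractory_fraction`, `n_intervals`.
#' @export
isi_histogram <- function(spikes, bin_ms = 1, refractory_ms = 2) {
  t <- spikes$spike_times
  if (length(t) < 2L) stop_invalid("need at least 2 spikes")
  isi <- diff(t) * 1000
  edges <- seq(0, (floor(max(isi) / bin_ms) + 1) * bin_ms, by = bin_ms)
  counts <- tabulate(findInterval(isi, edges, rightmost.closed = FALSE),
                     nbins = length(edges) - 1L)
  structure(list(bin_edges_ms = edges, counts = counts,
                 refractory_fraction = mean(isi < refractory_ms),
                 n_intervals = length(isi)),
            class = "isi_histogram")
}

#' Does a unit pass the refractory-period check?
#'
#' @param isi an `isi_histogram`.
#' @param max_fraction maximum tolerated fraction of sub-2 ms intervals,
#'   default 0.005.
#' @return logical.
#' @export
refractory_ok <- function(isi, max_fraction = 0.005) {
  isi$refractory_fraction < max_fraction
}

#' Spike-train autocorrelogram
#'
#' Counts of ordered spike pairs at each lag from -1000 ms to +1000 ms in
#' 1 ms bins (2001 bins; zero-lag self-pairs excluded). Symmetric by
#' construction. `N`, the peak of the signal, is the amplitude bound used
#' when fitting the skipping model.
#'
#' @param spikes a `spike_train` with at least 2 spikes.
#' @param max_lag_ms maximum lag, default 1000.
#' @param bin_ms bin width, default 1.
#' @return an object of class `autocorrelogram`: `lag_ms` (bin centres),
#'   `counts`, `n_spikes`, `bin_ms`, `N`.
#' @export
autocorrelogram <- function(spikes, max_lag_ms = 1000, bin_ms = 1) {
  check_scalar_pos(max_lag_ms, "max_lag_ms")
  check_scalar_pos(bin_ms, "bin_ms")
  t <- spikes$spike_times
  n <- length(t)
  if (n < 2L) stop_invalid("need at least 2 spikes")
  nb <- as.integer(round(max_lag_ms / bin_ms))
  lim_s <- (max_lag_ms + bin_ms / 2) / 1000
  pos <- integer(nb)   # bins centred at 1..nb * bin_ms
  zero <- 0L           # pairs with |lag| < bin_ms/2
  k <- 1L
  while (k < n) {
    d <- t[(k + 1L):n] - t[1L:(n - k)]
    d <- d[d < lim_s]
    if (!length(d)) break
    j <- as.integer(round(d * 1000 / bin_ms))
    zero <- zero + sum(j == 0L)
    j <- j[j >= 1L & j <= nb]
    pos <- pos + tabulate(j, nbins = nb)
    k <- k + 1L
  }
  counts <- c(rev(pos), 2L * zero, pos)
  structure(list(lag_ms = seq(-nb, nb) * bin_ms, counts = counts,
                 n_spikes = n, bin_ms = bin_ms, N = max(counts)),
            class = "autocorrelogram")
}

## The extended damped two-cosine autocorrelogram model.
## Unit convention: the cosine arguments take the lag in SECONDS with omega
## in rad/s (so the omega bounds [12 pi, 24 pi] and [6 pi, 12 pi] rad/s mean
## 6-12 Hz and 3-6 Hz), while the exponential decays take the lag in MS with
## tau in ms (bounds up to 5000 ms).
skipping_model_curve <- function(par, lag_ms) {
  x_s <- lag_ms / 1000
  ax <- abs(lag_ms)
  (par[["a1"]] * cos(par[["omega1"]] * x_s) +
     par[["a2"]] * cos(par[["omega2"]] * x_s)) * exp(-ax / par[["tau1"]]) +
    par[["b"]] +
    par[["c1"]] * exp(-ax / par[["tau2"]]) -
    par[["c2"]] * exp(-ax / par[["tau3"]])
}

#' Fit the damped two-cosine model to an autocorrelogram
#'
#' Bounded nonlinear least squares of
#' `y(x) = [a1 cos(w1 x) + a2 cos(w2 x)] exp(-|x|/tau1) + b +
#'  c1 exp(-|x|/tau2) - c2 exp(-|x|/tau3)`
#' to the non-normalized autocorrelogram. The theta-band cosine (`a1`,
#' `omega1` in 6-12 Hz) and the half-theta cosine (`a2`, `omega2` in 3-6 Hz)
#' superpose to produce alternating low/high peaks; `tau1` is their common
#' decay, (`c1`, `tau2`) the Poisson ISI exponential, (`c2`, `tau3`) the
#' refractory dip, and `b` the baseline. Amplitudes are bounded by `[0, N]`
#' with `N` the autocorrelogram peak; decay constants by `[0, 5000]`,
#' `[0, 100]` and `[0, 10]` ms; `omega1` by `[12 pi, 24 pi]` and `omega2` by
#' `[6 pi, 12 pi]` rad/s. The optimiser (Levenberg-Marquardt with box
#' constraints) is restarted from a grid of frequency initials spanning the
#' omega bounds, other initials taken from signal statistics; the lowest
#' residual wins. Deterministic.
#'
#' @param acorr an `autocorrelogram`.
#' @param n_starts integer vector of length 2: number of grid initials for
#'   `omega1` and `omega2` (default 5 x 5).
#' @param max_iter maximum optimiser iterations per start.
#' @return an object of class `skipping_fit` with the nine parameters,
#'   `residual_norm`, `converged`, `N`, `n_starts_converged`.
#' @export
fit_skipping_model <- function(acorr, n_starts = c(5L, 5L), max_iter = 200L) {
  y <- acorr$counts
  x <- acorr$lag_ms
  if (all(y == 0)) stop_invalid("autocorrelogram has no counts")
  N <- max(y)
  lower <- c(a1 = 0, a2 = 0, b = 0, c1 = 0, c2 = 0,
             omega1 = 12 * pi, omega2 = 6 * pi,
             tau1 = 0.1, tau2 = 0.1, tau3 = 0.1)
  upper <- c(a1 = N, a2 = N, b = N, c1 = N, c2 = N,
             omega1 = 24 * pi, omega2 = 12 * pi,
             tau1 = 5000, tau2 = 100, tau3 = 10)

  ## data-driven initials
  tail_mean <- mean(y[abs(x) >= 800])
  b0 <- min(max(tail_mean, 0), N)
  centre <- mean(y[abs(x) <= 20])
  c10 <- min(max(centre - b0, N / 20), N)
  peak_excess <- max(y[abs(x) >= 80 & abs(x) <= 160]) - b0
  a0 <- min(max(peak_excess, N / 50), N)

  mids <- function(lo, hi, k) lo + (seq_len(k) - 0.5) * (hi - lo) / k
  w1_grid <- mids(lower[["omega1"]], upper[["omega1"]], n_starts[1L])
  w2_grid <- mids(lower[["omega2"]], upper[["omega2"]], n_starts[2L])

  resid_fn <- function(p) y - skipping_model_curve(p, x)
  best <- NULL
  n_conv <- 0L
  for (w1 in w1_grid) for (w2 in w2_grid) {
    par0 <- c(a1 = 0.6 * a0, a2 = 0.4 * a0, b = b0, c1 = c10, c2 = c10,
              omega1 = w1, omega2 = w2, tau1 = 300, tau2 = 30, tau3 = 3)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = max_iter, nprint = 0)),
      error = function(e) NULL)
    if (is.null(fit)) next
    conv <- fit$info %in% 1:4
    if (conv) n_conv <- n_conv + 1L
    ## best converged start wins; a non-converged one is only a fallback
    better <- is.null(best) ||
      (conv && !best$converged) ||
      (conv == best$converged && fit$deviance < best$deviance)
    if (better)
      best <- list(par = fit$par, deviance = fit$deviance, converged = conv)
  }
  if (is.null(best)) stop_invalid("no optimiser start succeeded")
  p <- unlist(best$par)
  structure(c(as.list(p),
              list(residual_norm = sqrt(best$deviance),
                   converged = best$converged, N = N,
                   n_starts_converged = n_conv)),
            class = "skipping_fit")
}

#' Evaluate a fitted skipping model
#'
#' @param object a `skipping_fit`.
#' @param lag_ms lags (ms) at which to evaluate the model.
#' @param ... unused.
#' @return fitted autocorrelogram values.
#' @export
predict.skipping_fit <- function(object, lag_ms, ...) {
  skipping_model_curve(unlist(object[c("a1", "a2", "b", "c1", "c2", "omega1",
                                       "omega2", "tau1", "tau2", "tau3")]),
                       lag_ms)
}

#' @export
print.skipping_fit <- function(x, ...) {
  cat("Damped two-cosine autocorrelogram fit\n")
  cat(sprintf("  f_high %.2f Hz  f_low %.2f Hz  (ratio %.3f)\n",
              x$omega1 / (2 * pi), x$omega2 / (2 * pi), x$omega1 / x$omega2))
  cat(sprintf("  a1 %.2f  a2 %.2f  b %.2f  c1 %.2f  c2 %.2f\n",
              x$a1, x$a2, x$b, x$c1, x$c2))
  cat(sprintf("  tau1 %.0f ms  tau2 %.1f ms  tau3 %.2f ms\n",
              x$tau1, x$tau2, x$tau3))
  cat(sprintf("  residual norm %.1f  converged %s\n",
              x$residual_norm, x$converged))
  invisible(x)
}

#' Jump factor
#'
#' Relative contribution of the half-theta (low-frequency) cosine to the
#' high autocorrelogram peaks, `a2 / (a1 + a2)`; values above 0.5 mean the
#' slow interfering oscillation dominates the jump.
#'
#' @param fit a `skipping_fit` with `a1 + a2 > 0`.
#' @return jump factor in `[0, 1]`.
#' @export
jump_factor <- function(fit) {
  s <- fit$a1 + fit$a2
  if (s <= 0) stop_invalid("jump factor undefined: a1 + a2 = 0")
  fit$a2 / s
}

#' Frequency ratio of the two fitted cosines
#'
#' `omega1 / omega2`; a ratio near 2 verifies the superposition (in-phase /
#' anti-phase) account of the alternating peaks.
#'
#' @param fit a `skipping_fit`.
#' @return frequency ratio (within `[1, 4]` given the omega bounds).
#' @export
frequency_ratio <- function(fit) {
  if (fit$omega2 <= 0) stop_invalid("frequency ratio undefined: omega2 = 0")
  fit$omega1 / fit$omega2
}

## stationary part of the fitted model: damped oscillations + baseline,
## without the transient ISI and refractory exponentials
oscillatory_curve <- function(fit, lag_ms) {
  x_s <- lag_ms / 1000
  (fit$a1 * cos(fit$omega1 * x_s) + fit$a2 * cos(fit$omega2 * x_s)) *
    exp(-abs(lag_ms) / fit$tau1) + fit$b
}

## local maxima after the centre peak of the fitted curve: heights of the
## first local maxima following the first local minimum at positive lag
fitted_peaks_after_centre <- function(fit, max_lag_ms = 1000, step_ms = 0.5,
                                      component = c("oscillatory", "full")) {
  component <- match.arg(component)
  lag <- seq(0, max_lag_ms, by = step_ms)
  yy <- if (component == "oscillatory") oscillatory_curve(fit, lag)
        else predict(fit, lag)
  d <- diff(yy)
  mins <- which(d[-length(d)] < 0 & d[-1L] >= 0) + 1L
  if (!length(mins)) return(numeric(0))
  maxs <- which(d[-length(d)] > 0 & d[-1L] <= 0) + 1L
  maxs <- maxs[maxs > mins[1L]]
  list(height = yy[maxs], lag_ms = lag[maxs])
}

#' Theta-cycle skipping index (TS)
#'
#' Locates the first (P1) and second (P2) local maxima of the fitted
#' autocorrelogram model after the centre peak and returns
#' `TS = (P2 - P1) / max(P1, P2)`, which lies in `[-1, +1]`. TS is positive
#' when the second peak exceeds the first, i.e. when alternate theta cycles
#' are skipped. By default the peaks are measured on the stationary part of
#' the fitted model (the two damped cosines plus the baseline `b`): the ISI
#' and refractory exponentials are transients whose share of the curve at
#' the first peak is a fitting degeneracy, not theta structure, and keeping
#' them can flip the sign of a small TS. `mode = "full"` measures the
#' complete fitted curve, `mode = "raw"` the boxcar-smoothed raw counts.
#'
#' @param fit a converged `skipping_fit`.
#' @param acorr the fitted `autocorrelogram` (only needed for
#'   `mode = "raw"`).
#' @param mode `"oscillatory"` (default), `"full"` or `"raw"`.
#' @return TS in `[-1, 1]`.
#' @export
theta_skipping_index <- function(fit, acorr = NULL,
                                 mode = c("oscillatory", "full", "raw")) {
  mode <- match.arg(mode)
  if (!isTRUE(fit$converged)) stop_invalid("TS undefined: fit not converged")
  if (mode != "raw") {
    pk <- fitted_peaks_after_centre(fit, component = mode)
  } else {
    if (is.null(acorr)) stop_invalid("acorr needed when mode = 'raw'")
    pos <- acorr$lag_ms >= 0
    sm <- as.numeric(stats::filter(acorr$counts[pos], rep(0.2, 5)))
    lag <- acorr$lag_ms[pos]
    ok <- !is.na(sm)
    yy <- sm[ok]; lg <- lag[ok]
    d <- diff(yy)
    mins <- which(d[-length(d)] < 0 & d[-1L] >= 0) + 1L
    maxs <- which(d[-length(d)] > 0 & d[-1L] <= 0) + 1L
    maxs <- if (length(mins)) maxs[maxs > mins[1L]] else integer(0)
    pk <- list(height = yy[maxs], lag_ms = lg[maxs])
  }
  if (length(pk$height) < 2L)
    stop_invalid("TS undefined: fewer than two post-centre peaks")
  p1 <- max(pk$height[1L], 0)
  p2 <- max(pk$height[2L], 0)
  if (max(p1, p2) <= 0) stop_invalid("TS undefined: non-positive peaks")
  (p2 - p1) / max(p1, p2)
}

#' Derived indices of a skipping fit
#'
#' @param fit a `skipping_fit`.
#' @param acorr the fitted `autocorrelogram`.
#' @return an object of class `skipping_indices`: `jump_factor`,
#'   `frequency_ratio`, `ts_index` (`NA` if undefined), `f_high_hz`,
#'   `f_low_hz`.
#' @export
skipping_indices <- function(fit, acorr = NULL) {
  ts <- tryCatch(theta_skipping_index(fit, acorr), error = function(e) NA_real_)
  structure(list(jump_factor = tryCatch(jump_factor(fit),
                                        error = function(e) NA_real_),
                 frequency_ratio = frequency_ratio(fit),
                 ts_index = ts,
                 f_high_hz = fit$omega1 / (2 * pi),
                 f_low_hz = fit$omega2 / (2 * pi)),
            class = "skipping_indices")
}

## baseline + two exponentials, no oscillation: the null model of the
## oscillation significance test
fit_null_model <- function(acorr, max_iter = 200L) {
  y <- acorr$counts; x <- acorr$lag_ms
  N <- max(y)
  lower <- c(b = 0, c1 = 0, c2 = 0, tau2 = 0.1, tau3 = 0.1)
  upper <- c(b = N, c1 = N, c2 = N, tau2 = 100, tau3 = 10)
  b0 <- min(max(mean(y[abs(x) >= 800]), 0), N)
  c10 <- min(max(mean(y[abs(x) <= 20]) - b0, N / 20), N)
  par0 <- c(b = b0, c1 = c10, c2 = c10, tau2 = 30, tau3 = 3)
  resid_fn <- function(p)
    y - (p[["b"]] + p[["c1"]] * exp(-abs(x) / p[["tau2"]]) -
           p[["c2"]] * exp(-abs(x) / p[["tau3"]]))
  fit <- minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                            fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = max_iter, nprint = 0))
  fit$deviance
}

#' Test the significance of the fitted oscillation
#'
#' Nested-model F test comparing the full damped two-cosine fit with a null
#' fit holding only the baseline and the two exponentials: the five
#' oscillation parameters (a1, a2, omega1, omega2, tau1) must reduce the
#' residual sum of squares more than chance. Because the optimiser selects
#' the best frequencies within the bounds, use a stringent alpha.
#'
#' @param fit a `skipping_fit`.
#' @param acorr the fitted `autocorrelogram`.
#' @return a list: `F`, `df1`, `df2`, `p`.
#' @export
oscillation_f_test <- function(fit, acorr) {
  rss_full <- fit$residual_norm^2
  rss_null <- fit_null_model(acorr)
  df1 <- 5
  df2 <- length(acorr$counts) - 10
  Fs <- max((rss_null - rss_full) / df1, 0) / (rss_full / df2)
  list(F = Fs, df1 = df1, df2 = df2,
       p = stats::pf(Fs, df1, df2, lower.tail = FALSE))
}

#' @export
print.skipping_indices <- function(x, ...) {
  cat(sprintf("jump %.3f, ratio %.3f, TS %.3f\n",
              x$jump_factor, x$frequency_ratio, x$ts_index))
  invisible(x)
}

#' Classify a unit as theta-cycle skipping
#'
#' A unit is called theta-cycle skipping when the model fit converged, the
#' skipping index is positive, the jump factor reaches `jump_threshold`,
#' and the oscillation is statistically required by the data
#' ([oscillation_f_test()] p below `osc_alpha`). The default alpha is a
#' nominal 0.001 Bonferroni-corrected by the roughly 10^3 effective
#' frequency-decay combinations the bounded multi-start fit scans (about a
#' dozen resolvable omega1 cells times half a dozen omega2 cells times a
#' handful of tau1 scales): without that correction the fit dresses pure
#' count noise in a small spurious oscillation with nominal p down to 1e-4.
#'
#' @param fit a `skipping_fit`.
#' @param acorr the fitted `autocorrelogram`.
#' @param indices optional precomputed [skipping_indices()].
#' @param jump_threshold minimum jump factor, default 0.2.
#' @param osc_alpha significance level of the oscillation F test,
#'   default 1e-6 (nominal 0.001 / ~10^3 scanned hypotheses).
#' @return logical.
#' @export
classify_theta_skipping <- function(fit, acorr, indices = NULL,
                                    jump_threshold = 0.2, osc_alpha = 1e-6) {
  if (!isTRUE(fit$converged)) return(FALSE)
  if (is.null(indices)) indices <- skipping_indices(fit, acorr)
  !is.na(indices$ts_index) && indices$ts_index > 0 &&
    !is.na(indices$jump_factor) && indices$jump_factor >= jump_threshold &&
    oscillation_f_test(fit, acorr)$p < osc_alpha
}

#' Theta-modulation depth of a fit
#'
#' Relative depth of the fitted theta cosine against the baseline,
#' `a1 / b`; used to band units into theta-modulated (>= 0.3 by default)
#' and weakly theta-modulated (>= 0.1) — conventions, not measurements from
#' the source study, which never quantified these bands.
#'
#' @param fit a `skipping_fit`.
#' @return non-negative depth (Inf when `b` is 0 but `a1` > 0).
#' @export
theta_modulation_depth <- function(fit) {
  if (fit$b <= 0) return(if (fit$a1 > 0) Inf else 0)
  fit$a1 / fit$b
}
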