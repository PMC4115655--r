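#' @keywords internal
"_PACKAGE"

## Angular helpers. All public angles are degrees in [0, 360); signed
## differences live in (-180, 180].

wrap_deg <- function(x) x %% 360

#' Signed circular difference between two angles
#'
#' @param a,b angles in degrees.
#' @return `a - b` wrapped into (-180, 180].
#' @export
circ_diff_deg <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

#' Circular mean of angles in degrees
#'
#' @param theta_deg angles in degrees.
#' @return mean direction in [0, 360), or `NA` if the input is empty.
#' @export
circ_mean_deg <- function(theta_deg) {
  if (length(theta_deg) == 0L) return(NA_real_)
  th <- theta_deg * pi / 180
  wrap_deg(atan2(mean(sin(th)), mean(cos(th))) * 180 / pi)
}

## Index of the nearest element of sorted `grid` for each `x`
nearest_index <- function(x, grid) {
  i <- findInterval(x, grid, all.inside = TRUE)
  use_upper <- (x - grid[i]) > (grid[i + 1L] - x)
  out <- i + as.integer(use_upper)
  out[x <= grid[1L]] <- 1L
  out[x >= grid[length(grid)]] <- length(grid)
  out
}

stop_invalid <- function(...) stop(..., call. = FALSE)

check_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stop_invalid(name, " must be a positive scalar")
  invisible(x)
}
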