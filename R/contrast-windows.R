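# Time-frequency contrast summaries of labelled time-series ensembles:
# Gaussian-weighted time windows (band = 0) and Morlet energy projectors
# over a frequency band, applied in evoked / induced / per-trial modes.
# The machinery accepts any channel or source ensemble; the mathematics is
# identical either way.

#' Specify a time-frequency summary contrast
#'
#' @param time_segments list of `c(t1, t2)` peristimulus-ms segments (a
#'   degenerate segment with `t1 == t2` selects a single time point).
#' @param band_hz `c(f1, f2)` frequency band in Hz, or 0 for plain
#'   Gaussian-weighted time averaging of the signed signal.
#' @param mode `"evoked"` (energy of the trial average), `"induced"`
#'   (average of per-trial energies) or `"trials"` (one value per trial).
#' @param edge_fwhm_ms FWHM of the Gaussian edge applied to the window
#'   indicator (8 ms; a degenerate segment becomes a pure 8 ms FWHM
#'   Gaussian).
#' @return list of class `tf_contrast_spec`.
#' @export
tf_contrast_spec <- function(time_segments, band_hz = 0,
                             mode = c("evoked", "induced", "trials"),
                             edge_fwhm_ms = 8) {
  mode <- match.arg(mode)
  if (!is.list(time_segments)) time_segments <- list(time_segments)
  for (s in time_segments)
    if (length(s) != 2 || s[1] > s[2])
      stop("each time segment must be c(t1, t2) with t1 <= t2")
  if (!identical(band_hz, 0) && length(band_hz) == 1) band_hz <- rep(band_hz, 2)
  if (!identical(band_hz, 0)) {
    if (band_hz[1] <= 0 || band_hz[1] > band_hz[2])
      stop("band must be 0 or 0 < f1 <= f2")
  }
  structure(list(time_segments = time_segments, band_hz = band_hz,
                 mode = mode, edge_fwhm_ms = edge_fwhm_ms),
            class = "tf_contrast_spec")
}

#' Gaussian-edged time-window weights
#'
#' The indicator of the union of the time segments is convolved with a
#' Gaussian of `edge_fwhm_ms` FWHM and normalized to unit sum. A
#' degenerate (zero-length) segment yields a pure Gaussian of that FWHM,
#' so a single-time-point contrast has an 8 ms FWHM weighting by default.
#'
#' @param segments list of `c(t1, t2)` in ms (or a single `c(t1, t2)`).
#' @param time_axis epoch sample times in ms (uniform).
#' @param edge_fwhm_ms Gaussian edge FWHM in ms.
#' @return list of class `time_window_weights`: `weights` (sums to 1),
#'   `time_axis`, `centers`.
#' @export
build_time_weights <- function(segments, time_axis, edge_fwhm_ms = 8) {
  if (!is.list(segments)) segments <- list(segments)
  dt <- diff(time_axis[1:2])
  n <- length(time_axis)
  ind <- numeric(n)
  centers <- numeric(0)
  for (s in segments) {
    if (s[2] < time_axis[1] || s[1] > time_axis[n]) next
    if (s[1] == s[2]) {
      ind[which.min(abs(time_axis - s[1]))] <- 1
    } else {
      ind[time_axis >= s[1] & time_axis <= s[2]] <- 1
    }
    centers <- c(centers, mean(s))
  }
  if (sum(ind) == 0) stop("time segments do not overlap the epoch")
  sig <- .fwhm_to_sigma(edge_fwhm_ms) / dt
  k <- .gauss_kernel(sig)
  g <- if (length(k) > 1) as.vector(.sep_convolve(array(ind, c(n, 1)),
                                                  list(k, 1))) else ind
  g <- g / sum(g)
  structure(list(weights = g, time_axis = time_axis, centers = centers),
            class = "time_window_weights")
}

#' Weighted temporal average (band = 0 contrast)
#'
#' `sum_t g(t) * x(t)` per series. With unit-sum weights a constant series
#' returns that constant; a response antisymmetric about the window center
#' averages to zero even when strong.
#'
#' @param x numeric vector, or matrix/array with time as the last
#'   dimension.
#' @param weights a [build_time_weights] result (or bare numeric vector).
#' @return scalar, or array with the time dimension dropped.
#' @export
apply_time_contrast <- function(x, weights) {
  g <- if (inherits(weights, "time_window_weights")) weights$weights else
    as.numeric(weights)
  nt <- if (is.null(dim(x))) length(x) else dim(x)[length(dim(x))]
  if (nt != length(g))
    stop("weights length does not match the epoch (", nt, " samples)")
  if (is.null(dim(x))) return(sum(x * g))
  dm <- dim(x)
  y <- matrix(x, ncol = nt) %*% g
  if (length(dm) == 2) as.vector(y) else array(y, dm[-length(dm)])
}

#' Morlet energy contrast over a time window and frequency band
#'
#' A series of unit-energy Morlet projectors (1 Hz spacing across the
#' band, 7 cycles) summarizes the energy in the time window and band:
#' per trial, `energy = sum_f sum_t g(t) * |coef(f, t)|^2`. Mode
#' `"evoked"` computes it on the trial average (phase-locked energy),
#' `"induced"` averages per-trial energies (capturing non-phase-locked
#' activity as well), `"trials"` returns one value per trial. With
#' `band = 0` the specification routes to [apply_time_contrast] on the
#' trial average.
#'
#' @param x numeric array `[n_trials, n_units, n_time]` (units are
#'   channels or sources), or an [epoched_dataset].
#' @param spec a [tf_contrast_spec].
#' @param time_axis epoch times in ms (taken from the dataset if `x` is
#'   one).
#' @param n_cycles,freq_step Morlet projector parameters.
#' @return numeric vector of one value per unit (evoked/induced) or an
#'   `n_trials x n_units` matrix (trials mode).
#' @export
apply_energy_contrast <- function(x, spec, time_axis = NULL, n_cycles = 7,
                                  freq_step = 1) {
  if (inherits(x, "epoched_dataset")) {
    time_axis <- x$time_axis
    x <- x$data
  }
  if (is.null(time_axis)) stop("time_axis is required")
  dm <- dim(x)
  if (length(dm) != 3) stop("x must be trials x units x time")
  dt <- diff(time_axis[1:2])
  w <- build_time_weights(spec$time_segments, time_axis,
                          spec$edge_fwhm_ms)
  if (identical(spec$band_hz, 0)) {
    avg <- colMeans(x)                      # units x time
    return(apply_time_contrast(avg, w))
  }
  nyq <- 1000 / (2 * dt)
  if (spec$band_hz[2] >= nyq)
    stop("frequency band extends to or beyond the Nyquist limit")
  freqs <- seq(spec$band_hz[1], spec$band_hz[2], by = freq_step)
  energy_of <- function(series_mat) {
    # series_mat: n_series x n_time -> energy per series
    pw <- .morlet_power(series_mat, dt, freqs, n_cycles)$power
    tot <- 0
    for (fi in seq_along(freqs))
      tot <- tot + matrix(pw[, fi, ], nrow = nrow(series_mat)) %*% w$weights
    as.vector(tot)
  }
  if (spec$mode == "evoked") {
    avg <- colMeans(x)
    energy_of(avg)
  } else {
    per_trial <- matrix(NA_real_, dm[1], dm[2])
    flat <- matrix(aperm(x, c(2, 1, 3)), nrow = dm[1] * dm[2])
    # rows ordered unit-fastest: rebuild as (units*trials) x time
    e <- energy_of(flat)
    per_trial <- matrix(e, dm[2], dm[1])     # units x trials
    per_trial <- t(per_trial)
    if (spec$mode == "trials") per_trial else colMeans(per_trial)
  }
}
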