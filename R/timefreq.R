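# Morlet wavelet time-frequency decomposition and its two dimensionality
# reductions: channel-averaged time-frequency images and frequency-band
# averaged time-domain power datasets.

#' Specify a Morlet wavelet decomposition
#'
#' The complex Morlet wavelet at frequency `f` is
#' `w(t) = A * exp(i*2*pi*f*t) * exp(-t^2 / (2*sigma_t^2))` with
#' `sigma_t = n_cycles / (2*pi*f)`, normalized to unit total energy and
#' truncated at 5 sigma. `n_cycles` sets the temporal-frequency resolution
#' trade-off; values above 5 give stable power estimates (default 7).
#'
#' @param frequencies strictly increasing frequencies in Hz.
#' @param n_cycles number of cycles in the wavelet (>= 1).
#' @return list of class `morlet_spec`.
#' @export
morlet_spec <- function(frequencies, n_cycles = 7) {
  frequencies <- as.numeric(frequencies)
  if (any(frequencies <= 0)) stop("frequencies must be positive")
  if (any(diff(frequencies) <= 0))
    stop("frequencies must be strictly increasing")
  if (n_cycles < 1) stop("n_cycles must be at least 1")
  structure(list(frequencies = frequencies, n_cycles = n_cycles),
            class = "morlet_spec")
}

# Morlet wavelet power for a matrix of series (n_series x n_time).
# Reflection padding at the edges, FFT convolution, unit-energy wavelets.
# Returns list(power = array [n_series x n_freq x n_time], edge = samples
# within 5*sigma_t of either epoch edge, per frequency).
.morlet_power <- function(x, dt_ms, frequencies, n_cycles) {
  ns <- nrow(x); nt <- ncol(x)
  dt_s <- dt_ms / 1000
  nyq <- 1 / (2 * dt_s)
  if (any(frequencies >= nyq))
    stop("frequency at or above the Nyquist limit (", nyq, " Hz)")
  sig_t <- n_cycles / (2 * pi * frequencies)          # seconds
  hw <- pmin(ceiling(5 * sig_t / dt_s), nt - 1L)      # half-width, samples
  pad <- max(hw)
  # reflection padding (without repeating the edge sample)
  left <- x[, pmin(nt, pad + 1):2, drop = FALSE]
  right <- x[, (nt - 1):max(1, nt - pad), drop = FALSE]
  xp <- cbind(left, x, right)
  L <- ncol(xp)
  nfft <- stats::nextn(L + 2L * pad + 1L, 2)
  X <- stats::mvfft(t(unname(cbind(xp, matrix(0, ns, nfft - L)))))
  power <- array(NA_real_, c(ns, length(frequencies), nt))
  for (fi in seq_along(frequencies)) {
    h <- hw[fi]
    tau <- (-h:h) * dt_s
    w <- exp(2i * pi * frequencies[fi] * tau) *
      exp(-tau^2 / (2 * sig_t[fi]^2))
    w <- w / sqrt(sum(Mod(w)^2))                       # unit energy
    wfft <- stats::fft(c(w, complex(real = rep(0, nfft - length(w)))))
    Y <- stats::mvfft(wfft * X, inverse = TRUE) / nfft
    # conv result index k = sum_j xp[j] w[k-j+1]; the wavelet center sits
    # at offset h+1, so the coefficient for padded sample m is row m + h
    power[, fi, ] <- t(Mod(Y[pad + h + seq_len(nt), , drop = FALSE])^2)
  }
  list(power = power, edge = hw)
}

#' Morlet wavelet transform of an epoched dataset
#'
#' Per trial, channel and frequency, power is the squared magnitude of the
#' convolution with a unit-energy complex Morlet wavelet (reflection
#' padding at the epoch edges, support truncated at 5 sigma).
#'
#' @param ds an [epoched_dataset].
#' @param spec a [morlet_spec]; all frequencies must lie below Nyquist.
#' @return object of class `tf_decomposition`: `power`
#'   `[n_trials, n_channels, n_freq, n_time]`, `frequencies` (Hz), `time_axis`
#'   (ms), `edge_samples` per frequency, and the source dataset metadata.
#' @export
morlet_transform <- function(ds, spec) {
  d <- dim(ds$data)
  dt <- diff(ds$time_axis[1:2])
  x <- matrix(aperm(ds$data, c(3, 1, 2)), nrow = d[3])  # time x (trial*chan)
  res <- .morlet_power(t(x), dt, spec$frequencies, spec$n_cycles)
  nf <- length(spec$frequencies)
  pw <- array(res$power, c(d[1], d[2], nf, d[3]))
  structure(list(power = pw, frequencies = spec$frequencies,
                 time_axis = ds$time_axis, edge_samples = res$edge,
                 channel_names = ds$channel_names,
                 channel_types = ds$channel_types,
                 condition_labels = ds$condition_labels,
                 bad_channels = ds$bad_channels,
                 rejected_trials = ds$rejected_trials,
                 layout = ds$layout, n_cycles = spec$n_cycles),
            class = "tf_decomposition")
}

#' @export
print.tf_decomposition <- function(x, ...) {
  d <- dim(x$power)
  cat("<tf_decomposition> ", d[1], " trials x ", d[2], " channels x ",
      d[3], " frequencies x ", d[4], " samples\n", sep = "")
  invisible(x)
}

#' Channel-averaged time-frequency images
#'
#' Averaging power over a channel subset (or selecting a single channel)
#' reduces the 4D decomposition to one 2D frequency x time image per trial.
#'
#' @param tf a `tf_decomposition`.
#' @param channels channel names or indices; all must be good.
#' @return list of 2D [stat_image]s (Hz x ms), one per trial.
#' @export
tf_image_from_channels <- function(tf, channels) {
  idx <- if (is.character(channels)) match(channels, tf$channel_names)
  else as.integer(channels)
  if (length(idx) == 0L || anyNA(idx)) stop("empty or unknown channel selection")
  if (any(tf$bad_channels[idx])) stop("selection includes bad channels")
  d <- dim(tf$power)
  df <- if (length(tf$frequencies) > 1) diff(tf$frequencies[1:2]) else 1
  dt <- diff(tf$time_axis[1:2])
  lapply(seq_len(d[1]), function(tr) {
    pl <- tf$power[tr, idx, , , drop = FALSE]
    img <- apply(array(pl, dim(pl)[-1]), c(2, 3), mean)
    stat_image(img, pixdim = c(df, dt), units = c("Hz", "ms"),
               origin = c(tf$frequencies[1], tf$time_axis[1]),
               provenance = list(trial = tr,
                                 condition = tf$condition_labels[tr]))
  })
}

#' Average power over a frequency band into a time-domain dataset
#'
#' Mean power over the grid frequencies inside `band_hz`, per trial,
#' channel and time point; the result is an ordinary time-domain dataset
#' (power waveforms) that can be exported to images like any other.
#'
#' @param tf a `tf_decomposition`.
#' @param band_hz `c(f1, f2)` band limits in Hz (inclusive).
#' @return An [epoched_dataset] of band power waveforms.
#' @export
band_average_to_dataset <- function(tf, band_hz) {
  sel <- which(tf$frequencies >= band_hz[1] & tf$frequencies <= band_hz[2])
  if (length(sel) == 0L)
    stop("frequency band does not intersect the frequency grid")
  d <- dim(tf$power)
  pw <- tf$power[, , sel, , drop = FALSE]
  out <- array(0, c(d[1], d[2], d[4]))
  for (fi in seq_along(sel)) out <- out + pw[, , fi, ]
  out <- out / length(sel)
  epoched_dataset(out, tf$time_axis, tf$channel_names, tf$channel_types,
                  tf$condition_labels, tf$layout, tf$bad_channels,
                  tf$rejected_trials)
}
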