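# Synthetic data with known ground truth: sensor montages, epoched datasets
# with dipolar-topography effects and structured noise, and smooth Gaussian
# null fields of known FWHM.

# run expr under a temporary RNG state seeded with `seed`; global RNG state
# is restored afterwards so generators behave as pure functions
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a hemispherical sensor montage
#'
#' Quasi-uniform sensors on an upper hemisphere of radius 0.09 m (a
#' spherical head model) via a Fibonacci lattice with a small seeded
#' angular jitter, projected to a 2D layout with [project_to_layout];
#' nasion and left/right preauricular analogue fiducials sit on the
#' equator of the sphere.
#'
#' @param n_channels number of sensors (>= 4).
#' @param seed integer seed; the montage is a pure function of
#'   `(n_channels, seed)`.
#' @param radius head sphere radius in meters.
#' @return list with `positions3d` (n x 3, meters), `layout`
#'   ([channel_layout]), `fiducials` (3 x 3 named matrix), and
#'   `channel_names`.
#' @export
gen_montage <- function(n_channels, seed = 1L, radius = 0.09) {
  if (n_channels < 4L) stop("a montage needs at least 4 channels")
  .with_seed(seed, {
    i <- seq_len(n_channels) - 0.5
    z <- 1 - 0.85 * i / n_channels        # cos(theta): cap to near-equator
    golden <- pi * (3 - sqrt(5))
    az <- i * golden + runif(1, 0, 2 * pi)
    az <- az + rnorm(n_channels, 0, 0.005)  # seeded jitter, keeps points distinct
    st <- sqrt(pmax(0, 1 - z^2))
    pos <- radius * cbind(st * cos(az), st * sin(az), z)
    nm <- sprintf("CH%03d", seq_len(n_channels))
    rownames(pos) <- nm
    fid <- radius * rbind(nasion = c(0, 1, 0), lpa = c(-1, -0.05, 0),
                          rpa = c(1, -0.05, 0))
    fid <- fid / sqrt(rowSums(fid^2)) * radius
    list(positions3d = pos,
         layout = project_to_layout(pos, channel_names = nm),
         fiducials = fid, channel_names = nm)
  })
}

#' Specify a synthetic epoched experiment
#'
#' An experiment is a sum of spatio-temporal effects plus structured noise.
#' Each effect has a scalp topography (sum of signed Gaussian bumps over 2D
#' layout distance), a Gaussian temporal envelope at a given latency, an
#' optional carrier oscillation that is either phase-locked across trials
#' (evoked) or has uniform random phase per trial (induced), and one
#' amplitude weight per condition. Noise is AR(1) in time with
#' exponentially decaying spatial correlation over the layout.
#'
#' @param n_trials trials per condition.
#' @param conditions condition labels.
#' @param n_channels number of sensors.
#' @param dt_ms sampling interval, ms.
#' @param epoch_ms epoch window `c(t_min, t_max)` in peristimulus ms.
#' @param effects list of effect descriptors; see [sim_effect].
#' @param noise_sd marginal sensor noise SD (same units as the signal).
#' @param spatial_corr_length spatial correlation length on the unit-disc
#'   layout (`exp(-d / l)`); 0 disables spatial correlation.
#' @param ar1 temporal AR(1) coefficient in (-1, 1).
#' @param seed integer seed.
#' @return list of class `simulation_spec`.
#' @export
simulation_spec <- function(n_trials = 50, conditions = c("A", "B"),
                            n_channels = 32, dt_ms = 2,
                            epoch_ms = c(-100, 400),
                            effects = list(),
                            noise_sd = 1, spatial_corr_length = 0.3,
                            ar1 = 0.3, seed = 1L) {
  spec <- structure(list(n_trials = n_trials, conditions = conditions,
                         n_channels = n_channels, dt_ms = dt_ms,
                         epoch_ms = epoch_ms, effects = effects,
                         noise_sd = noise_sd,
                         spatial_corr_length = spatial_corr_length,
                         ar1 = ar1, seed = as.integer(seed)),
                    class = "simulation_spec")
  .validate_sim_spec(spec)
  spec
}

#' Describe one synthetic effect
#'
#' @param centers k x 2 matrix of bump centers in layout coordinates.
#' @param center_signs sign per bump (+1 / -1), recycled.
#' @param spread spatial Gaussian SD of each bump in layout units.
#' @param amplitude peak amplitude (topography is normalized to peak 1).
#' @param latency_ms center of the temporal envelope, peristimulus ms.
#' @param fwhm_ms temporal full width at half maximum of the envelope.
#' @param frequency_hz carrier frequency; `NULL` for a non-oscillatory bump.
#' @param phase_locked if `TRUE` the carrier phase is 0 on every trial;
#'   otherwise it is drawn uniformly on `[0, 2*pi)` per trial.
#' @param condition_weights named or positional amplitude multipliers, one
#'   per condition.
#' @return list of class `sim_effect`.
#' @export
sim_effect <- function(centers = matrix(c(0, 0.4), 1), center_signs = 1,
                       spread = 0.25, amplitude = 1, latency_ms = 150,
                       fwhm_ms = 50, frequency_hz = NULL,
                       phase_locked = TRUE, condition_weights = c(1, 1)) {
  structure(list(centers = matrix(centers, ncol = 2),
                 center_signs = center_signs, spread = spread,
                 amplitude = amplitude, latency_ms = latency_ms,
                 fwhm_ms = fwhm_ms, frequency_hz = frequency_hz,
                 phase_locked = phase_locked,
                 condition_weights = condition_weights),
            class = "sim_effect")
}

.validate_sim_spec <- function(spec) {
  err <- function(f) stop("invalid simulation spec field: ", f)
  if (spec$n_trials < 1) err("n_trials")
  if (spec$n_channels < 4) err("n_channels")
  if (spec$dt_ms <= 0) err("dt_ms")
  if (diff(spec$epoch_ms) <= 0) err("epoch_ms")
  if (spec$noise_sd < 0) err("noise_sd")
  if (spec$spatial_corr_length < 0) err("spatial_corr_length")
  if (abs(spec$ar1) >= 1) err("ar1")
  for (e in spec$effects) {
    if (e$spread <= 0) err("spread")
    if (e$fwhm_ms <= 0) err("fwhm_ms")
    if (!is.null(e$frequency_hz) && e$frequency_hz <= 0) err("frequency_hz")
    if (length(e$condition_weights) != length(spec$conditions))
      err("condition_weights")
    if (!all(is.finite(e$condition_weights))) err("condition_weights")
  }
  invisible(TRUE)
}

# topography of one effect over the layout, normalized to peak |1|
.effect_topography <- function(effect, layout) {
  pos <- layout$positions2d
  signs <- rep_len(effect$center_signs, nrow(effect$centers))
  topo <- numeric(nrow(pos))
  for (k in seq_len(nrow(effect$centers))) {
    d2 <- (pos[, 1] - effect$centers[k, 1])^2 +
      (pos[, 2] - effect$centers[k, 2])^2
    topo <- topo + signs[k] * exp(-d2 / (2 * effect$spread^2))
  }
  m <- max(abs(topo))
  if (m > 0) topo <- topo / m
  topo
}

#' Generate a synthetic epoched dataset
#'
#' Each trial is the sum of the spec's effects plus structured noise. The
#' noise has the specified marginal SD per channel, AR(1) dependence along
#' time, and `exp(-d / l)` spatial correlation across the layout. The
#' result is a pure function of the spec (including its seed).
#'
#' @param spec a [simulation_spec].
#' @param montage optional result of [gen_montage]; generated from the
#'   spec's seed when missing.
#' @return An [epoched_dataset] with `n_trials * length(conditions)` trials.
#' @export
gen_dataset <- function(spec, montage = NULL) {
  .validate_sim_spec(spec)
  if (is.null(montage)) montage <- gen_montage(spec$n_channels, spec$seed)
  time_axis <- seq(spec$epoch_ms[1], spec$epoch_ms[2], by = spec$dt_ms)
  nt <- length(time_axis)
  nch <- spec$n_channels
  ntr <- spec$n_trials * length(spec$conditions)
  labels <- rep(spec$conditions, each = spec$n_trials)

  topos <- lapply(spec$effects, .effect_topography, layout = montage$layout)
  envs <- lapply(spec$effects, function(e) {
    s <- .fwhm_to_sigma(e$fwhm_ms)
    exp(-(time_axis - e$latency_ms)^2 / (2 * s^2))
  })

  # spatial correlation factor for the noise
  L <- NULL
  if (spec$spatial_corr_length > 0 && spec$noise_sd > 0) {
    d <- as.matrix(stats::dist(montage$layout$positions2d))
    C <- exp(-d / spec$spatial_corr_length)
    diag(C) <- diag(C) + 1e-8
    sdv <- sqrt(diag(C))
    C <- C / tcrossprod(sdv)          # unit marginal variance
    L <- t(chol(C))
  }
  a <- spec$ar1

  .with_seed(spec$seed + 1L, {
    data <- array(0, c(ntr, nch, nt))
    for (tr in seq_len(ntr)) {
      cond_i <- match(labels[tr], spec$conditions)
      x <- matrix(0, nch, nt)
      for (j in seq_along(spec$effects)) {
        e <- spec$effects[[j]]
        w <- e$condition_weights[cond_i]
        carrier <- 1
        if (!is.null(e$frequency_hz)) {
          ph <- if (e$phase_locked) 0 else runif(1, 0, 2 * pi)
          carrier <- cos(2 * pi * e$frequency_hz *
                           (time_axis - e$latency_ms) / 1000 + ph)
        }
        x <- x + (w * e$amplitude) * tcrossprod(topos[[j]],
                                                envs[[j]] * carrier)
      }
      if (spec$noise_sd > 0) {
        eps <- matrix(rnorm(nch * nt), nch, nt)
        if (!is.null(L)) eps <- L %*% eps
        n <- matrix(0, nch, nt)
        n[, 1] <- eps[, 1]                       # stationary start
        if (nt > 1) {
          sc <- sqrt(1 - a^2)
          for (k in 2:nt) n[, k] <- a * n[, k - 1] + sc * eps[, k]
        }
        x <- x + spec$noise_sd * n
      }
      data[tr, , ] <- x
    }
    epoched_dataset(data, time_axis, montage$channel_names,
                    rep("EEG", nch), labels, montage$layout)
  })
}

#' Generate a smooth Gaussian null field of known FWHM
#'
#' White Gaussian noise is convolved with a separable Gaussian kernel of
#' the stated per-dimension FWHM (in voxels, truncated at 4 sigma, computed
#' on a padded array so the interior is free of border effects) and
#' rescaled to unit pointwise variance. With `fwhm = 0` the field is plain
#' white noise. Pure function of `(shape, fwhm, seed)`.
#'
#' @param shape integer vector of dimensions (each >= 4).
#' @param fwhm_voxels kernel FWHM per dimension in voxels (scalar recycled).
#' @param seed integer seed.
#' @return numeric array of dimension `shape`.
#' @export
gen_null_volume <- function(shape, fwhm_voxels = 0, seed = 1L) {
  shape <- as.integer(shape)
  if (any(shape <= 0)) stop("all dimensions must be positive")
  if (any(shape < 4L)) stop("all dimensions must be at least 4")
  fwhm <- rep_len(fwhm_voxels, length(shape))
  if (any(fwhm < 0)) stop("fwhm must be non-negative")
  sig <- .fwhm_to_sigma(fwhm)
  kern <- lapply(sig, .gauss_kernel)
  pad <- vapply(kern, function(k) (length(k) - 1L) %/% 2L, integer(1))
  .with_seed(seed, {
    x <- array(rnorm(prod(shape + 2L * pad)), shape + 2L * pad)
    for (j in seq_along(shape)) {
      if (length(kern[[j]]) == 1L) next
      op <- .conv_operator(shape[j], pad[j], kern[[j]])
      x <- .apply_along(x, op, j)
    }
    # remove any residual padding on dims with fwhm 0
    if (!all(dim(x) == shape)) {
      idx <- lapply(seq_along(shape), function(j)
        seq_len(shape[j]) + (dim(x)[j] - shape[j]) %/% 2L)
      x <- do.call(`[`, c(list(x), idx, list(drop = FALSE)))
    }
    sdfac <- sqrt(prod(vapply(kern, function(k) sum(k^2), numeric(1))))
    array(x / sdfac, shape)
  })
}
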