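# Shared fixture builders: everything is generated in code at test time.

fix_montage <- function(n = 16, seed = 1) gen_montage(n, seed)

# small epoched dataset with an optional evoked effect in condition A
fix_dataset <- function(n_trials = 4, n_channels = 16, dt_ms = 2,
                        epoch_ms = c(-100, 300), noise_sd = 1,
                        effect_amp = 0, seed = 1, ar1 = 0.3,
                        spatial_corr_length = 0.3) {
  effects <- if (effect_amp > 0)
    list(sim_effect(centers = matrix(c(0, 0.4), 1), amplitude = effect_amp,
                    latency_ms = 150, fwhm_ms = 50,
                    condition_weights = c(1, 0)))
  else list()
  gen_dataset(simulation_spec(
    n_trials = n_trials, conditions = c("A", "B"),
    n_channels = n_channels, dt_ms = dt_ms, epoch_ms = epoch_ms,
    effects = effects, noise_sd = noise_sd, ar1 = ar1,
    spatial_corr_length = spatial_corr_length, seed = seed))
}

# hand-built tiny dataset with fully controlled values
fix_manual_dataset <- function(data, conditions, seed = 1,
                               rejected = rep(FALSE, dim(data)[1])) {
  d <- dim(data)
  m <- gen_montage(d[2], seed)
  epoched_dataset(data, seq(0, by = 2, length.out = d[3]),
                  m$channel_names, rep("EEG", d[2]), conditions, m$layout,
                  rejected_trials = rejected)
}

# ensembles of noisy oscillatory trials for energy-contrast tests
fix_oscillation_trials <- function(n_trials = 50, n_units = 8,
                                   time_axis = seq(-100, 400, by = 2),
                                   freq = 20, amp = 2, noise_sd = 1,
                                   phase_locked = TRUE, seed = 11) {
  nt <- length(time_axis)
  env <- exp(-(time_axis - 150)^2 / (2 * (40 / 2.3548)^2))
  set.seed(seed)
  x <- array(0, c(n_trials, n_units, nt))
  for (tr in seq_len(n_trials)) {
    ph <- if (phase_locked) 0 else runif(1, 0, 2 * pi)
    sig <- amp * env * cos(2 * pi * freq * (time_axis - 150) / 1000 + ph)
    for (u in seq_len(n_units)) x[tr, u, ] <- sig + rnorm(nt, 0, noise_sd)
  }
  x
}
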