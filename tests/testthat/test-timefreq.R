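tf_fixture <- function(freqs = seq(5, 40), n_trials = 2, f0 = 20,
                       amp = 1, seed = 1) {
  m <- gen_montage(6, seed)
  taxis <- seq(-100, 400, by = 2)
  x <- array(0, c(n_trials, 6, length(taxis)))
  for (tr in seq_len(n_trials)) for (ch in 1:6)
    x[tr, ch, ] <- amp * sin(2 * pi * f0 * taxis / 1000)
  ds <- epoched_dataset(x, taxis, m$channel_names,
                        condition_labels = rep("A", n_trials),
                        layout = m$layout)
  list(ds = ds, taxis = taxis, freqs = freqs)
}

test_that("Morlet power peaks at the carrier and scales quadratically", {
  fx <- tf_fixture()
  tf <- morlet_transform(fx$ds, morlet_spec(fx$freqs))
  expect_true(all(tf$power >= 0))
  mid <- which.min(abs(fx$taxis - 150))
  expect_equal(fx$freqs[which.max(tf$power[1, 1, , mid])], 20)

  fx2 <- tf_fixture(amp = 2)
  tf2 <- morlet_transform(fx2$ds, morlet_spec(fx$freqs))
  ratio <- tf2$power / pmax(tf$power, 1e-300)
  expect_equal(max(abs(ratio - 4)), 0, tolerance = 1e-6)

  expect_error(morlet_transform(fx$ds, morlet_spec(c(10, 300))), "Nyquist")
})

test_that("wideband summed power is proportional to time-domain energy", {
  # interior window; dense grid covering the signal content
  taxis <- seq(0, 1000, by = 2)
  m <- gen_montage(4, 1)
  mk <- function(f) {
    sig <- sin(2 * pi * f * taxis / 1000)
    x <- array(0, c(1, 4, length(taxis)))
    for (ch in 1:4) x[1, ch, ] <- sig
    epoched_dataset(x, taxis, m$channel_names, condition_labels = "A",
                    layout = m$layout)
  }
  spec <- morlet_spec(seq(2, 120), n_cycles = 7)
  interior <- which(taxis >= 200 & taxis <= 800)
  ratio <- vapply(c(11, 37, 83), function(f) {
    tf <- morlet_transform(mk(f), spec)
    num <- sum(tf$power[1, 1, , interior])
    den <- sum(mk(f)$data[1, 1, interior]^2)
    num / den
  }, numeric(1))
  expect_lt(max(ratio) / min(ratio), 1.05)
})

test_that("power is covariant under time shifts away from the edges", {
  taxis <- seq(0, 1000, by = 2)
  m <- gen_montage(4, 1)
  set.seed(3)
  base <- as.vector(stats::filter(rnorm(length(taxis) + 40), rep(0.2, 5),
                                  sides = 2))[21:(length(taxis) + 20)]
  k <- 25  # shift in samples
  x1 <- array(base, c(1, 4, length(taxis)))
  x2 <- x1
  x2[, , (k + 1):length(taxis)] <- x1[, , 1:(length(taxis) - k)]
  mk <- function(x) epoched_dataset(x, taxis, m$channel_names,
                                    condition_labels = "A",
                                    layout = m$layout)
  spec <- morlet_spec(seq(15, 40, by = 5))
  tf1 <- morlet_transform(mk(x1), spec)
  tf2 <- morlet_transform(mk(x2), spec)
  edge <- max(tf1$edge_samples) + k
  interior <- (edge + 1):(length(taxis) - edge)
  dev <- abs(tf2$power[1, 1, , interior + k] - tf1$power[1, 1, , interior])
  expect_lt(max(dev), 1e-6 * max(tf1$power))
})

test_that("power envelope tracks a squared amplitude modulation", {
  taxis <- seq(0, 2000, by = 2)
  m <- gen_montage(4, 1)
  envel <- exp(-(taxis - 1000)^2 / (2 * 150^2))
  sig <- envel * sin(2 * pi * 20 * taxis / 1000)
  x <- array(0, c(1, 4, length(taxis)))
  for (ch in 1:4) x[1, ch, ] <- sig
  ds <- epoched_dataset(x, taxis, m$channel_names, condition_labels = "A",
                        layout = m$layout)
  tf <- morlet_transform(ds, morlet_spec(c(18, 20, 22)))
  interior <- which(taxis >= 300 & taxis <= 1700)
  expect_gt(cor(tf$power[1, 1, 2, interior], envel[interior]^2), 0.99)
})

test_that("channel averaging and band averaging reduce dimensions correctly", {
  fx <- tf_fixture(n_trials = 3)
  tf <- morlet_transform(fx$ds, morlet_spec(fx$freqs))
  # single-channel selection equals that channel's plane
  one <- tf_image_from_channels(tf, "CH001")
  expect_equal(one[[1]]$data, tf$power[1, 1, , ])
  expect_equal(dim(one[[1]]$data), c(length(fx$freqs), length(fx$taxis)))
  # identical channels: mean of two equals either
  two <- tf_image_from_channels(tf, c("CH001", "CH002"))
  expect_equal(two[[1]]$data, one[[1]]$data, tolerance = 1e-10)
  expect_error(tf_image_from_channels(tf, character(0)), "empty")
  tf$bad_channels[1] <- TRUE
  expect_error(tf_image_from_channels(tf, "CH001"), "bad")

  # band averaging: single frequency equals its plane; constant over
  # frequency returns that profile; output is a valid exportable dataset
  tf$bad_channels[1] <- FALSE
  bd <- band_average_to_dataset(tf, c(20, 20))
  expect_equal(bd$data[1, 1, ], tf$power[1, 1, 16, ])
  expect_true(validate_dataset(bd)$pass)
  out <- withr::local_tempdir()
  man <- dataset_to_volumes(bd, out, name = "band")
  expect_equal(nrow(man), 3)
  expect_error(band_average_to_dataset(tf, c(300, 400)), "intersect")
})
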