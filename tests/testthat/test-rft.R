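test_that("white-noise residuals have the analytic roughness", {
  # independent unit-variance voxels: var of first differences = 2,
  # FWHM = sqrt(4 log 2 / 2) ~ 1.177 voxels
  vols <- array(NA_real_, c(40, 24, 24, 12))
  for (i in 1:40) vols[i, , , ] <- gen_null_volume(c(24, 24, 12), 0,
                                                   seed = 900 + i)
  mod <- fit_glm(vols, build_design("one-sample", n = 40))
  sm <- estimate_smoothness(mod)
  expect_true(all(abs(sm$fwhm - sqrt(2 * log(2))) / sqrt(2 * log(2)) < 0.05))
})

test_that("resel counts follow the cuboid formulas and scaling laws", {
  R <- resel_counts(c(64, 64, 64), 8)
  expect_equal(R[4], 512)                       # (64/8)^3
  expect_equal(R[1], 1)
  expect_equal(R[2], 3 * 64 / 8)
  expect_equal(R[3], 3 * (64 / 8)^2)
  # halving linear extent halves R1 terms and quarters R2 (exact)
  Rh <- resel_counts(c(32, 32, 32), 8)
  expect_equal(Rh[2], R[2] / 2)
  expect_equal(Rh[3], R[3] / 4)
  # irregular masks use the bounding box for low orders, count for top
  Rm <- resel_counts(c(10, 10), c(2, 2), n_mask = 60)
  expect_equal(Rm[3], 60 / 4)
  expect_error(resel_counts(c(8, 8), 0), "positive")
})

test_that("EC densities obey the field-type identities", {
  u <- seq(2, 6, by = 0.5)
  # F(1, nu) equals the two-sided t(nu) field at sqrt(u)
  for (d in 0:3)
    expect_equal(ec_density(u^2, d, "F", c(1, 17)),
                 2 * ec_density(u, d, "t", 17), tolerance = 1e-9)
  # t converges to Gaussian as dof grows
  for (d in 0:3)
    expect_equal(ec_density(3, d, "t", 1e6), ec_density(3, d, "Gaussian"),
                 tolerance = 1e-4)
  # d = 0 is the uncorrected upper tail
  expect_equal(ec_density(u, 0, "Gaussian"), pnorm(u, lower.tail = FALSE))
  expect_equal(ec_density(u, 0, "t", 9), pt(u, 9, lower.tail = FALSE))
  expect_equal(ec_density(u, 0, "F", c(3, 20)),
               pf(u, 3, 20, lower.tail = FALSE))
})

test_that("peak p reduces to the uncorrected tail on a point domain", {
  u <- c(1.5, 2.5, 4)
  expect_equal(rft_peak_p(u, "Gaussian", resels = c(1, 0, 0, 0)),
               pnorm(u, lower.tail = FALSE))
  # monotone nonincreasing in u
  us <- seq(0, 10, by = 0.1)
  ps <- rft_peak_p(us, "Gaussian", resels = resel_counts(c(32, 32, 20), 6))
  expect_true(all(diff(ps) <= 1e-12))
  expect_error(rft_peak_p(3, "Gaussian", resels = c(1, -1, 0, 0)),
               "non-negative")
})

test_that("probit-Gaussianized t thresholds approach Gaussian thresholds", {
  R <- resel_counts(c(32, 32, 20), 6)
  ut <- rft_threshold(0.05, "t", dof = 1000, resels = R)
  ug <- rft_threshold(0.05, "Gaussian", resels = R)
  # map the t threshold through its tail probability onto the z scale
  zt <- qnorm(pt(ut, 1000, lower.tail = FALSE), lower.tail = FALSE)
  expect_equal(zt, ug, tolerance = 1e-3)
})

test_that("corrected thresholds are never above Bonferroni once smooth", {
  shape <- c(32, 32, 20); V <- prod(shape)
  ubonf_g <- qnorm(0.05 / V, lower.tail = FALSE)
  for (f in c(3, 4, 6, 8, 12)) {
    R <- resel_counts(shape, f, n_mask = V)
    # package threshold (with its Bonferroni floor) never exceeds Bonferroni
    u_pkg <- rft_threshold(0.05, "Gaussian", resels = R, n_vox = V)
    expect_lte(u_pkg, ubonf_g + 1e-8)
  }
  # the pure RFT threshold is strictly more sensitive once past the
  # crossover smoothness (~3.3 voxels FWHM for Gaussian fields on this
  # mask, ~4.5 for t fields with 22 df, whose heavier-tailed EC densities
  # shift the crossover up)
  for (f in c(4, 6, 8, 12)) {
    R <- resel_counts(shape, f, n_mask = V)
    expect_lt(rft_threshold(0.05, "Gaussian", resels = R), ubonf_g)
  }
  for (f in c(6, 8, 12)) {
    R <- resel_counts(shape, f, n_mask = V)
    expect_lt(rft_threshold(0.05, "t", dof = 22, resels = R),
              qt(0.05 / V, 22, lower.tail = FALSE))
  }
})

test_that("cluster p has the boundary value and is decreasing in extent", {
  R <- resel_counts(c(32, 32, 20), 6, n_mask = 32 * 32 * 20)
  fw <- rep(6, 3)
  uc <- qnorm(0.001, lower.tail = FALSE)
  Em <- sum(vapply(0:3, function(d) R[d + 1] * ec_density(uc, d, "Gaussian"),
                   numeric(1)))
  expect_equal(rft_cluster_p(0, uc, "Gaussian", resels = R, fwhm = fw,
                             n_vox = 32 * 32 * 20),
               1 - exp(-Em), tolerance = 1e-10)
  ks <- seq(0, 2000, by = 50)
  ps <- vapply(ks, function(k)
    rft_cluster_p(k, uc, "Gaussian", resels = R, fwhm = fw,
                  n_vox = 32 * 32 * 20), numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_error(rft_cluster_p(10, -1, "Gaussian", resels = R, fwhm = fw,
                             n_vox = 100), "positive")
})

test_that("peak-level FWER is calibrated on smooth nulls (reduced grid)", {
  # Gaussian field, known smoothness: empirical FWER within the
  # calibration band at nominal 0.05
  shape <- c(32, 32, 20)
  R <- resel_counts(shape, 6, n_mask = prod(shape))
  u <- rft_threshold(0.05, "Gaussian", resels = R, n_vox = prod(shape))
  hits <- 0; nrep <- 200
  for (r in seq_len(nrep))
    if (max(gen_null_volume(shape, 6, seed = 3000 + r)) > u) hits <- hits + 1
  expect_gte(hits / nrep, 0.02)
  expect_lte(hits / nrep, 0.09)

  # t field, estimated smoothness, full pipeline at reduced size
  rt <- simulate_fwer_null(n_sim = 150, shape = c(32, 32, 10), fwhm = 4,
                           contrast_type = "t", seed = 2)
  expect_gte(rt$fwer, 0.02 - 2 * rt$se)
  expect_lte(rt$fwer, 0.09)
})

test_that("topological reports find injected effects and respect windows", {
  shape <- c(32, 32, 20)
  bump <- array(0, shape)
  cx <- c(20, 11, 8)
  idx <- as.matrix(expand.grid(1:32, 1:32, 1:20))
  bump[idx] <- 6 * exp(-colSums((t(idx) - cx)^2) / (2 * 2.5^2))
  des <- build_design("two-sample", groups = c(12, 12))
  hits <- 0; nrep <- 12
  for (r in seq_len(nrep)) {
    imgs <- array(NA_real_, c(24, shape))
    for (i in 1:24)
      imgs[i, , , ] <- gen_null_volume(shape, 6, seed = 5000 + 24 * r + i) +
        (i <= 12) * bump
    mod <- fit_glm(imgs, des)
    con <- compute_contrast(mod, c(1, -1), "F")
    sm <- estimate_smoothness(mod)
    tab <- topological_report(con, sm, alpha = 0.05)
    top <- tab[1, ]
    if (nrow(tab) > 0 && top$significant &&
        sqrt(sum((c(top$x, top$y, top$z) + 1 - cx)^2)) <= 2)
      hits <- hits + 1
  }
  expect_gte(hits, nrep - 1)   # >= 95%-style recovery on the batch

  # window restriction never weakens the peak p of a peak inside it
  imgs <- array(NA_real_, c(24, shape))
  for (i in 1:24)
    imgs[i, , , ] <- gen_null_volume(shape, 6, seed = 7000 + i) +
      (i <= 12) * bump
  mod <- fit_glm(imgs, des)
  con <- compute_contrast(mod, c(1, -1), "F")
  sm <- estimate_smoothness(mod)
  tab <- topological_report(con, sm)
  win <- array(FALSE, shape); win[14:26, 5:17, 4:12] <- TRUE
  tabw <- topological_report(con, sm, window = win)
  expect_lte(tabw$p_fwe_peak[1], tab$p_fwe_peak[1])
  expect_error(topological_report(con, sm, window = array(FALSE, shape)),
               "disjoint")

  # pure-noise batch: mostly no significant rows at alpha 0.05
  sig <- 0
  for (r in 1:20) {
    imgs <- array(NA_real_, c(10, c(16, 16, 10)))
    for (i in 1:10)
      imgs[i, , , ] <- gen_null_volume(c(16, 16, 10), 0, seed = 11000 + 10 * r + i)
    mod <- fit_glm(imgs, build_design("one-sample", n = 10))
    con <- compute_contrast(mod, 1, "t")
    sm <- estimate_smoothness(mod)
    tab <- topological_report(con, sm, alpha = 0.05, cluster_p = 0.01)
    if (nrow(tab) > 0 && any(tab$significant)) sig <- sig + 1
  }
  expect_lte(sig, 4)  # ~0.95 probability of none, with binomial headroom
})
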