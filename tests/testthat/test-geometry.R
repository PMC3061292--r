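test_that("icosphere subdivision has the right counts and topology", {
  m0 <- icosphere(0)
  expect_equal(nrow(m0$vertices), 12)
  expect_equal(nrow(m0$faces), 20)
  for (lev in 0:4) {
    m <- icosphere(lev)
    expect_equal(nrow(m$vertices), 10 * 4^lev + 2)
    e <- rbind(m$faces[, 1:2], m$faces[, 2:3], m$faces[, c(3, 1)])
    e <- unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
    expect_equal(nrow(m$vertices) - nrow(e) + nrow(m$faces), 2)
    expect_equal(sqrt(rowSums(m$vertices^2)),
                 rep(1, nrow(m$vertices)), tolerance = 1e-12)
  }
  expect_error(icosphere(-1), "non-negative")
})

test_that("layout projection preserves azimuth and polar-angle ordering", {
  # apex maps to the origin
  pts <- rbind(c(0, 0, 1), c(1, 0, 1), c(0, 1, 1), c(1, 1, 0.5)) * 0.09
  lay <- project_to_layout(pts)
  expect_equal(unname(lay$positions2d[1, ]), c(0, 0), tolerance = 1e-12)
  # ring at equal polar angle -> equal planar radii
  az <- seq(0, 2 * pi, length.out = 9)[-9]
  ring <- 0.09 * cbind(sin(0.7) * cos(az), sin(0.7) * sin(az),
                       rep(cos(0.7), 8))
  lr <- project_to_layout(rbind(ring, c(0, 0, 0.09)))
  rr <- sqrt(rowSums(lr$positions2d[1:8, ]^2))
  expect_lt(diff(range(rr)), 1e-12)
  # azimuth preserved
  expect_equal(atan2(lr$positions2d[1:8, 2], lr$positions2d[1:8, 1]),
               atan2(ring[, 2], ring[, 1]), tolerance = 1e-12)
  expect_error(project_to_layout(rbind(c(0, 0, 0), c(0, 0, 1))),
               "coincident")
})

test_that("landmark fit recovers exact rigid motions and rejects reflections", {
  fid <- rbind(nasion = c(0, 0.1, 0), lpa = c(-0.08, 0, 0),
               rpa = c(0.08, 0, 0), extra = c(0, 0.02, 0.09))
  ident <- landmark_fit(fid, fid)
  expect_equal(ident$rotation, diag(3), tolerance = 1e-12)
  expect_equal(ident$translation, c(0, 0, 0), tolerance = 1e-12)
  expect_lt(ident$rms, 1e-12)

  ang <- 23 * pi / 180
  R0 <- matrix(c(cos(ang), -sin(ang), 0, sin(ang), cos(ang), 0, 0, 0, 1),
               3, byrow = TRUE)
  t0 <- c(0.01, -0.004, 0.006)
  fit <- landmark_fit(fid, sweep(fid %*% t(R0), 2, t0, "+"))
  expect_lt(max(abs(fit$rotation - R0)), 1e-9)
  expect_lt(max(abs(fit$translation - t0)), 1e-9)

  # reflected target: solution is still a proper rotation, residual large
  refl <- fid %*% diag(c(-1, 1, 1))
  rfit <- landmark_fit(fid, refl)
  expect_equal(det(rfit$rotation), 1, tolerance = 1e-10)
  expect_gt(rfit$rms, 1e-3)

  expect_error(landmark_fit(fid[1:2, ], fid[1:2, ]), "three")
  coll <- rbind(a = c(0, 0, 0), b = c(1, 0, 0), c = c(2, 0, 0)) * 0.01
  expect_error(landmark_fit(coll, coll), "collinear")
})

test_that("landmark fit is equivariant under a global rotation", {
  set.seed(2)
  src <- matrix(rnorm(15, sd = 0.05), 5, 3)
  ang <- 0.4
  R0 <- matrix(c(cos(ang), 0, sin(ang), 0, 1, 0, -sin(ang), 0, cos(ang)),
               3, byrow = TRUE)
  dst <- sweep(src %*% t(R0), 2, c(0.01, 0.02, 0), "+")
  base <- landmark_fit(src, dst)
  th <- 1.1
  Q <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
              3, byrow = TRUE)
  conj <- landmark_fit(src %*% t(Q), dst %*% t(Q))
  expect_equal(conj$rotation, Q %*% base$rotation %*% t(Q),
               tolerance = 1e-9)
})

test_that("ICP is a fixed point on aligned data and recovers small motions", {
  ico <- icosphere(3)
  head <- sweep(ico$vertices, 2, c(0.07, 0.095, 0.08), "*")
  head <- head[head[, 3] > -0.02, ]
  set.seed(4)
  pts <- head[sample(nrow(head), 200), ]

  fx <- icp_align(pts, head, init = rigid_transform(), tol = 1e-9)
  expect_true(fx$converged)
  expect_lte(fx$iterations, 2)
  expect_lt(rotation_angle(fx$transform), 1e-9)
  expect_lt(sqrt(sum(fx$transform$translation^2)), 1e-9)

  ang <- 5 * pi / 180
  Rz <- matrix(c(cos(ang), -sin(ang), 0, sin(ang), cos(ang), 0, 0, 0, 1),
               3, byrow = TRUE)
  t0 <- c(0.004, 0.002, -0.001)
  moved <- sweep(pts %*% t(Rz), 2, t0, "+")
  fid <- rbind(nasion = c(0, 0.095, 0), lpa = c(-0.07, 0, 0),
               rpa = c(0.07, 0, 0))
  init <- landmark_fit(sweep(fid %*% t(Rz), 2, t0, "+") +
                         matrix(rnorm(9, 0, 0.002), 3), fid)
  icp <- icp_align(moved, head, init = init, tol = 1e-9, max_iter = 100)
  Rtrue <- t(Rz)
  ttrue <- -as.vector(t(Rz) %*% t0)
  angerr <- acos(pmin(1, (sum(diag(t(icp$transform$rotation) %*% Rtrue)) - 1) / 2))
  expect_lt(angerr * 180 / pi, 0.5)
  expect_lt(1000 * sqrt(sum((icp$transform$translation - ttrue)^2)), 1)
  # RMS is non-increasing across iterations
  expect_true(all(diff(icp$rms_trace) <= 1e-12))
  expect_error(icp_align(matrix(0, 0, 3), head), "empty")
})
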