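test_that("scalp-map interpolation is exact on constant and affine fields", {
  m <- fix_montage(32, 5)
  cst <- interpolate_scalp_map(rep(7.25, 32), m$layout)
  expect_equal(dim(cst$data), c(64, 64))
  inhull <- !is.na(cst$data)
  expect_true(all(abs(cst$data[inhull] - 7.25) < 1e-9))

  # affine field reproduced at every in-hull pixel
  pos <- m$layout$positions2d
  vals <- 2 + 3 * pos[, 1] - 1.5 * pos[, 2]
  img <- interpolate_scalp_map(vals, m$layout)
  grid <- image_grid(m$layout)
  pred <- outer(grid$xo, grid$yo, function(x, y) 2 + 3 * x - 1.5 * y)
  expect_lt(max(abs(img$data - pred), na.rm = TRUE), 1e-9)

  # triangle centroid gets the mean of the vertex values
  tri <- channel_layout(rbind(c(0, 0), c(1, 0), c(0, 1)))
  g <- image_grid(tri, n_pixels = 31, margin = 0)
  ti <- interpolate_scalp_map(c(1, 2, 4), tri, grid = g)
  cx <- which.min(abs(g$xo - 1 / 3)); cy <- which.min(abs(g$yo - 1 / 3))
  expect_equal(ti$data[cx, cy], mean(c(1, 2, 4)), tolerance = 0.15)

  expect_error(interpolate_scalp_map(1:2, channel_layout(rbind(c(0, 0),
                                                               c(1, 0)))),
               "3 good channels")
})

test_that("bad channels interpolate or leave propagating holes", {
  m <- fix_montage(32, 5)
  vals <- rnorm(32)
  bad <- rep(FALSE, 32); bad[7] <- TRUE
  smooth_mode <- interpolate_scalp_map(vals, m$layout, bad_channels = bad)
  remove_mode <- interpolate_scalp_map(vals, m$layout, bad_channels = bad,
                                       bad_channel_mode = "remove")
  extra <- sum(is.na(remove_mode$data)) - sum(is.na(smooth_mode$data))
  expect_gt(extra, 0)  # removing a channel punches a hole
  # holes persist through smoothing at identical voxels
  sm <- gaussian_smooth_image(remove_mode, c(8, 8))
  expect_identical(is.na(sm$data), is.na(remove_mode$data))
})

test_that("volume export writes one image per condition or retained trial", {
  ds <- fix_dataset(n_trials = 5, n_channels = 16, seed = 2)
  ds$rejected_trials[3] <- TRUE
  out <- withr::local_tempdir()

  man_avg <- dataset_to_volumes(average_epochs(ds), out, name = "avg")
  expect_equal(nrow(man_avg), 2)           # one image per condition
  expect_true(all(file.exists(man_avg$file)))
  expect_setequal(basename(dirname(man_avg$file)), c("A", "B"))

  man_ep <- dataset_to_volumes(ds, out, name = "ep")
  expect_equal(nrow(man_ep), sum(!ds$rejected_trials))

  # z-dimension is peristimulus time; frames equal single scalp maps
  img <- read_stat_image(man_avg$file[man_avg$condition == "A"])
  expect_equal(dim(img$data)[3], length(ds$time_axis))
  av <- average_epochs(ds)
  k <- 37
  frame <- interpolate_scalp_map(av$data[1, , k], ds$layout)
  expect_equal(img$data[, , k], frame$data, tolerance = 1e-6)
  expect_equal(img$pixdim[3], diff(ds$time_axis[1:2]), tolerance = 1e-6)
})

test_that("time-window averages match brute-force summation", {
  ds <- fix_dataset(n_trials = 4, n_channels = 16, seed = 3)
  av <- average_epochs(ds)
  sel <- which(ds$time_axis >= 100 & ds$time_axis <= 180)
  direct <- 0
  for (k in sel) direct <- direct + av$data[1, , k]
  direct <- direct / length(sel)
  img <- average_time_window_image(av, c(100, 180), condition = "A")
  ref <- interpolate_scalp_map(direct, ds$layout)
  expect_equal(img$data, ref$data, tolerance = 1e-12)

  # degenerate window = single frame; time-constant data = any frame
  k1 <- which(ds$time_axis == 100)
  one <- average_time_window_image(av, c(100, 100), condition = "A")
  f1 <- interpolate_scalp_map(av$data[1, , k1], ds$layout)
  expect_equal(one$data, f1$data, tolerance = 1e-12)
  expect_error(average_time_window_image(av, c(900, 950)), "intersect")
})

test_that("planar gradiometer pairs combine by root-mean-square", {
  expect_equal(combine_planar_rms(3, 4), sqrt(25 / 2))
  expect_equal(combine_planar_rms(0, 0), 0)
  a <- rnorm(20)
  expect_equal(combine_planar_rms(a, a), abs(a))
  expect_error(combine_planar_rms(1:3, 1:2), "pairs")
})

test_that("smoothing conserves mass, commutes with scaling, keeps constants", {
  img <- stat_image(array(0, c(41, 41)), pixdim = c(2, 2),
                    units = c("mm", "mm"))
  img$data[21, 21] <- 5
  sm <- gaussian_smooth_image(img, c(8, 8))
  expect_lt(abs(sum(sm$data) - 5) / 5, 1e-6)

  cst <- stat_image(array(3.3, c(30, 30)), pixdim = c(2, 2),
                    units = c("mm", "mm"))
  expect_lt(max(abs(gaussian_smooth_image(cst, c(10, 10))$data - 3.3)),
            1e-12)

  set.seed(6)
  noisy <- stat_image(array(rnorm(900), c(30, 30)), pixdim = c(2, 2),
                      units = c("mm", "mm"))
  s1 <- gaussian_smooth_image(noisy, c(6, 6))$data
  noisy$data <- 4 * noisy$data
  s4 <- gaussian_smooth_image(noisy, c(6, 6))$data
  expect_equal(s4, 4 * s1, tolerance = 1e-12)
  expect_error(gaussian_smooth_image(cst, c(8, 8, 8)), "per image dimension")
})

test_that("NIfTI stat images round-trip data, pixdim and field metadata", {
  arr <- array(rnorm(64 * 64 * 10), c(64, 64, 10))
  arr[5, 5, 5] <- NA
  img <- stat_image(arr, pixdim = c(1.5, 1.5, 2), units = c("mm", "mm", "ms"),
                    origin = c(-10, -10, -100),
                    field = list(type = "F", dof = c(1, 22)))
  f <- withr::local_tempfile(fileext = ".nii")
  write_stat_image(img, f)
  back <- read_stat_image(f)
  expect_equal(back$data, img$data, tolerance = 1e-6)
  expect_true(is.na(back$data[5, 5, 5]))
  expect_equal(back$pixdim, img$pixdim, tolerance = 1e-6)
  expect_equal(back$units, img$units)
  expect_equal(back$field$type, "F")
  expect_equal(back$field$dof, c(1, 22))
})
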