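# Synthetic generators: seeded determinism, forward-model geometry, and
# rejection of non-physical truth.

test_that("generators are bit-identical under a fixed seed", {
  a <- make_linescan(velocity = 500, flux = 80, hematocrit = 0.3,
                     duration = 0.1, noise_sd = 0.05, seed = 7)
  b <- make_linescan(velocity = 500, flux = 80, hematocrit = 0.3,
                     duration = 0.1, noise_sd = 0.05, seed = 7)
  expect_identical(a$intensity, b$intensity)
  h1 <- make_hemo(duration = 30, event_times = 10, noise_sd = 0.02,
                  seed = 3)
  h2 <- make_hemo(duration = 30, event_times = 10, noise_sd = 0.02,
                  seed = 3)
  expect_identical(h1$data, h2$data)
  v1 <- make_volume(shape = c(40, 40, 40), target_density = 1, seed = 5)
  v2 <- make_volume(shape = c(40, 40, 40), target_density = 1, seed = 5)
  expect_identical(v1$voxels, v2$voxels)
})

test_that("line-scan stripes encode velocity, flux and haematocrit geometrically", {
  # stationary RBCs: constant-position shadows, one per requested count
  k0 <- make_linescan(velocity = 0, flux = 4, duration = 1, seed = 1,
                      psf_sigma = 0)
  img <- k0$intensity[, k0$segments$along[1]:k0$segments$along[2]]
  dark_cols <- colMeans(img) < 0.5
  expect_identical(img[1, ], img[nrow(img), ])  # zero slope
  expect_equal(sum(diff(c(FALSE, dark_cols)) == 1), 4)  # four bands
  # moving RBCs: stripe advances velocity*dt/px columns per line
  k <- make_linescan(velocity = 500, flux = 80, hematocrit = 0.3,
                     dt_line = 0.001, px = 0.2, duration = 0.05, seed = 1,
                     psf_sigma = 0)
  i2 <- k$intensity[, k$segments$along[1]:k$segments$along[2]]
  shift <- 500 * 0.001 / 0.2  # 2.5 px per line
  r1 <- i2[1, 11:60]; r9 <- i2[9, 11 + 8 * shift + seq_len(50) - 1]
  expect_equal(r9, r1, tolerance = 1e-6)
  expect_error(make_linescan(velocity = 500, flux = 80, diameter = -1))
  expect_error(make_linescan(velocity = 1, flux = 1, hematocrit = 1.4))
})

test_that("movie generator produces flat traces without events and rejects bad ROIs", {
  m <- make_movie(n_frames = 30, events = NULL, noise_sd = 0, seed = 1)
  expect_true(all(m$roi_traces == m$truth$baseline_F))
  ev <- data.frame(roi = 1, time = 2, amp = 1.0)
  m2 <- make_movie(n_frames = 80, frame_rate = 10, events = ev,
                   noise_sd = 0, seed = 1)
  expect_equal(max(m2$roi_traces) / m2$truth$baseline_F - 1, 1.0,
               tolerance = 0.01)
  expect_error(make_movie(roi_centres = list(c(2, 2))), "ROI")
  expect_error(make_movie(n_frames = 30, frame_rate = 10,
                          events = data.frame(roi = 1, time = 99,
                                              amp = 1)))
})

test_that("volume generator hits the target density and encodes radii in the distance map", {
  for (sd in 1:5) {
    v <- make_volume(shape = c(60, 60, 60), target_density = 1, seed = sd)
    expect_gt(v$truth$density, 0.9 * 1)
    expect_lt(v$truth$density, 1.1 * 1)
  }
  v <- make_volume(shape = c(40, 40, 40), voxel_size = 1,
                   segments = list(list(p1 = c(20.5, 20.5, 0),
                                        p2 = c(20.5, 20.5, 40),
                                        radius = 2.5)))
  # distance map of the background measured at the axis equals the radius
  dmap <- distance_transform(!v$voxels)
  expect_equal(dmap[21, 21, 20], 3, tolerance = 0.2)  # 2.5 + half voxel
  expect_error(make_volume(shape = c(40, 40, 40), segments = list()))
  expect_error(make_volume(shape = c(40, 40, 40),
                           segments = list(list(p1 = c(1, 1, 1),
                                                p2 = c(5, 5, 5),
                                                radius = -2))))
})

test_that("hemo generator yields a constant CMRO2 without events and the stated masks", {
  h <- make_hemo(duration = 30, noise_sd = 0, seed = 1)
  h <- derive_channels(h)
  expect_lt(diff(range(h$data$CMRO2)), 1e-10)
  expect_equal(h$data$CMRO2[1], h$truth$cmro2_baseline)
  # 30% duty-cycle locomotion -> rest fraction ~70% minus padding
  h2 <- make_hemo(duration = 100, locomotion_bouts =
                    list(c(10, 10), c(40, 10), c(70, 10)), seed = 1)
  mask <- segment_rest(h2, pad = 0)
  expect_equal(mean(mask), 0.7, tolerance = 0.01)
  mask_pad <- segment_rest(h2, pad = 2)
  expect_equal(mean(!mask_pad), 0.42, tolerance = 0.01)  # 3 x 14 s
  expect_error(make_hemo(duration = 60,
                         locomotion_bouts = list(c(10, 10), c(15, 10))))
})
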