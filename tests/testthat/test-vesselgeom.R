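# Skeletonization, morphometry and tissue-distance distributions.

test_that("a single cylinder yields the right centerline, radii and density", {
  v <- make_volume(shape = c(60, 60, 60), voxel_size = 1,
                   segments = list(list(p1 = c(30.5, 30.5, 0),
                                        p2 = c(30.5, 30.5, 60),
                                        radius = 2.5)))
  s <- skeletonize_volume(v)
  expect_true(all(abs(s$radii - 2.5) <= 0.5))       # within half a voxel
  expect_equal(s$length, 60, tolerance = 0.05)
  # 60 um of vessel in (60 um)^3 -> 60/216000 um^-2 = 0.2778 m/mm^3
  expect_equal(capillary_density(s), v$truth$density, tolerance = 0.05)
  expect_equal(capillary_density(s, "um_per_um3"),
               capillary_density(s) / 1e3)
  # straight-tube skeleton length ~ endpoint distance
  zr <- range(s$points[, 3])
  expect_lt(abs(s$length - (diff(zr) + 1)), sqrt(3))
  expect_error(skeletonize_volume(array(FALSE, c(10, 10, 10))))
})

test_that("two crossing tubes produce a branch point", {
  v <- make_volume(shape = c(40, 40, 40), voxel_size = 1, segments = list(
    list(p1 = c(20.5, 20.5, 0), p2 = c(20.5, 20.5, 40), radius = 2),
    list(p1 = c(0, 20.5, 20.5), p2 = c(40, 20.5, 20.5), radius = 2)))
  s <- skeletonize_volume(v)
  expect_gt(sum(s$is_branch), 0)
  bp <- s$points[s$is_branch, , drop = FALSE]
  # branch point sits near the crossing (21, 21, 21)
  expect_lt(min(sqrt(rowSums(sweep(bp, 2, c(21, 21, 21))^2))), 4)
})

test_that("network density is recovered within 5 percent across seeds", {
  errs <- vapply(1:8, function(sd) {
    v <- make_volume(shape = c(70, 70, 70), voxel_size = 1,
                     target_density = 1, seed = sd)
    s <- skeletonize_volume(v)
    capillary_density(s) / v$truth$density - 1
  }, numeric(1))
  expect_lt(max(abs(errs)), 0.05)
})

test_that("diameter-by-depth profiles localize deep large vessels", {
  v <- make_volume(shape = c(50, 50, 60), voxel_size = 1, segments = list(
    list(p1 = c(15.5, 25.5, 5), p2 = c(15.5, 25.5, 15), radius = 2),
    list(p1 = c(35.5, 25.5, 45), p2 = c(35.5, 25.5, 55), radius = 4)))
  s <- skeletonize_volume(v)
  prof <- diameter_depth_profile(s, bin = 10)
  expect_true(all(prof$depth_hi - prof$depth_lo == 10))
  # a uniform network is flat; here the deep bin must be larger
  shallow <- prof$mean_diameter[prof$depth_lo == 0 | prof$depth_lo == 10]
  deep <- prof$mean_diameter[prof$depth_lo == 40 | prof$depth_lo == 50]
  expect_gt(mean(deep, na.rm = TRUE), mean(shallow, na.rm = TRUE) + 2)
  # empty bins are missing, not zero
  expect_true(all(is.na(prof$mean_diameter[prof$n == 0])))
  # half-open bins never double count
  expect_equal(sum(prof$n), nrow(s$points))
})

test_that("distance distribution matches the analytic field of a centered cylinder", {
  v <- make_volume(shape = c(60, 60, 60), voxel_size = 1,
                   segments = list(list(p1 = c(30.5, 30.5, 0),
                                        p2 = c(30.5, 30.5, 60),
                                        radius = 2.5)))
  dmap <- distance_transform(v$voxels)
  xs <- (1:60) - 0.5
  radial <- sqrt(outer((xs - 30)^2, (xs - 30)^2, `+`))
  # analytic: distance to the nearest foreground voxel of the tube; off
  # the tube this is close to (radial distance - radius), within a voxel
  # the map measures distance to the nearest vessel voxel center, so it
  # can exceed the surface distance by up to the voxel discretization
  bgv <- radial > 4
  err <- abs(dmap[, , 30][bgv] - (radial[bgv] - 2.5))
  expect_lt(stats::median(err), 0.75)
  expect_lt(max(err), sqrt(3))
  # all-vessel volume: distances all zero
  allv <- array(TRUE, c(12, 12, 12))
  expect_true(all(distance_transform(allv) == 0))
})

test_that("distance centiles are ordered and shrink with density", {
  p95 <- vapply(c(0.5, 1.5, 3), function(dens) {
    v <- make_volume(shape = c(90, 90, 90), voxel_size = 1,
                     target_density = dens, seed = 11)
    dd <- tissue_distance_distribution(v, substack = 40, n = 5, seed = 2)
    expect_true(all(diff(dd$centiles) >= 0))
    unname(dd$centiles["p95"])
  }, numeric(1))
  expect_true(all(diff(p95) < 0))
  v <- make_volume(shape = c(30, 30, 30), voxel_size = 1,
                   target_density = 1, seed = 1)
  expect_error(tissue_distance_distribution(v, substack = 50, n = 2))
})

test_that("movie diameters are exact on straight tubes and invariant to rotation", {
  m <- make_movie(ny = 64, nx = 64, n_frames = 8, px = 0.5, diameter = 5,
                  seed = 1)
  d <- frame_diameter_trace(m)
  expect_true(all(abs(d$value - 5) < 0.2))
  # gain invariance
  m2 <- m; m2$lumen <- 0.4 * m2$lumen
  d2 <- frame_diameter_trace(m2)
  expect_equal(d2$value, d$value, tolerance = 0.01)
  # 90-degree rotation invariance
  m3 <- m
  m3$lumen <- aperm(m$lumen, c(2, 1, 3))
  d3 <- frame_diameter_trace(m3)
  expect_equal(mean(d3$value), mean(d$value), tolerance = 0.05)
})

test_that("a diameter step is recovered at the right frame", {
  diam <- c(rep(4, 6), rep(6, 6))
  m <- make_movie(ny = 64, nx = 64, n_frames = 12, px = 0.5,
                  diameter = diam, seed = 2)
  d <- frame_diameter_trace(m)
  expect_true(all(abs(d$value - diam) < 0.3))
  expect_equal(which(diff(d$value) > 1), 6)
})

test_that("an oblique tube gives the same diameter as an axis-aligned one", {
  # 45-degree tube rendered directly into the lumen channel
  px <- 0.5
  n <- 80
  xs <- (1:n - 0.5) * px
  g <- expand.grid(y = xs, x = xs)
  dist45 <- abs(g$y - g$x) / sqrt(2)
  fr <- matrix(0.05 + 0.95 * pmin(1, pmax(0, (2.5 - dist45) / (px / 2) + 0.5)),
               n, n)
  m <- make_movie(ny = n, nx = n, n_frames = 2, px = px, diameter = 5,
                  seed = 3)
  m$lumen <- array(rep(fr, 2), c(n, n, 2))
  d <- frame_diameter_trace(m)
  expect_equal(mean(d$value), 5, tolerance = 0.05)
})
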