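# Radial diffusion-consumption model: closed-form, conservation and
# consistency properties.

test_that("zero consumption gives a uniform steady profile at the boundary value", {
  m <- oxygen_model(C_cap = 20, Vmax = 0, r_max = 15, Km = 1)
  p <- steady_profile(m)
  expect_true(all(abs(p$C - 20) < 1e-8))
  expect_equal(p$midpoint$C, 20, tolerance = 1e-8)
})

test_that("steady solve matches the Krogh zero-order closed form (Km -> 0, no wall)", {
  m <- oxygen_model(C_cap = 40, Vmax = 2, r_max = 12, wall = 0, Km = 1e-6)
  p <- steady_profile(m)
  D <- 9.24e-8 * 1e12 / 60           # um^2/s
  V <- 2 * 1000 / 60                 # uM/s
  krogh <- 40 - (V / (2 * D)) *
    (12^2 * log(p$r / 2.5) - (p$r^2 - 2.5^2) / 2)
  expect_lt(max(abs(p$C - krogh)) / 40, 0.01)
})

test_that("steady-state mass balance holds to better than 0.5 percent", {
  for (spec in list(c(14, 2, 14.4), c(21, 2, 21.2), c(42, 3, 14.4),
                    c(14, 3, 29.3))) {
    p <- steady_profile(oxygen_model(spec[1], spec[2], spec[3]))
    expect_lt(p$flux_imbalance, 0.005)
  }
})

test_that("halving the grid spacing changes the steady profile by <0.1 percent", {
  m1 <- oxygen_model(14, 2, 14.4, n_cells = 200)
  m2 <- oxygen_model(14, 2, 14.4, n_cells = 400)
  p1 <- steady_profile(m1); p2 <- steady_profile(m2)
  expect_lt(abs(p1$midpoint$C - p2$midpoint$C) / p2$midpoint$C, 0.001)
})

test_that("time march and direct steady solve agree", {
  m <- oxygen_model(14, 2, 14.4)
  pn <- steady_profile(m, method = "newton")
  pm <- steady_profile(m, method = "march")
  expect_equal(pm$midpoint$C, pn$midpoint$C, tolerance = 1e-4)
})

test_that("midpoint oxygen and consumption are monotone in Vmax, r_max and C_cap", {
  grid <- expand.grid(C_cap = c(14, 18, 22), Vmax = c(1, 2, 3),
                      r_max = c(10, 14.4, 20))
  mid <- apply(grid, 1, function(g)
    steady_profile(oxygen_model(g["C_cap"], g["Vmax"], g["r_max"],
                                n_cells = 150))$midpoint$C)
  dim(mid) <- c(3, 3, 3)  # C_cap x Vmax x r_max
  # increasing in C_cap
  expect_true(all(apply(mid, c(2, 3), diff) > 0))
  # decreasing in Vmax and in r_max
  expect_true(all(apply(mid, c(1, 3), diff) < 0))
  expect_true(all(apply(mid, c(1, 2), diff) < 0))
})

test_that("steady concentration profile is non-increasing in radius", {
  p <- steady_profile(oxygen_model(14, 2, 20))
  expect_true(all(diff(p$C) <= 1e-10))
  expect_true(all(p$VO2_frac >= 0 & p$VO2_frac <= 1))
})

test_that("time to steady state behaves like a diffusion time", {
  # pure diffusion: time scales roughly with (r_max - r_c)^2 / D
  t_small <- time_to_steady(oxygen_model(14, 0.5, 10))
  t_big <- time_to_steady(oxygen_model(14, 0.5, 20))
  expect_gt(t_big, t_small)
  # dimensional scale: domain 11.9 um, D = 1540 um^2/s -> well under a second
  m <- oxygen_model(14, 0, 14.4)
  expect_lt(time_to_steady(m), 10 * (14.4 - 2.5)^2 / 1540)
})

test_that("calibrate_rmax inverts steady_profile and is monotone in Vmax", {
  m <- oxygen_model(14, 2, 18)
  target <- steady_profile(m)$midpoint$VO2_frac
  r <- calibrate_rmax(oxygen_model(14, 2, 10), target)
  expect_equal(r, 18, tolerance = 0.05 / 18)
  r3 <- calibrate_rmax(oxygen_model(14, 3, 10), target)
  expect_lt(r3, r)
  expect_error(calibrate_rmax(oxygen_model(14, 2, 10), 0.99,
                              bracket = c(4, 5)))
})

test_that("centile sweep matches independent per-spacing solves and is monotone", {
  m <- oxygen_model(14, 2, 14.4, n_cells = 150)
  sp <- c(10, 14.4, 20, 29)
  sw <- centile_sweep(m, sp, centiles = c(50, 70, 80, 95))
  for (i in seq_along(sp)) {
    mi <- oxygen_model(14, 2, sp[i], n_cells = 150)
    expect_equal(sw$midpoint_C[i], steady_profile(mi)$midpoint$C,
                 tolerance = 1e-10)
  }
  expect_true(all(diff(sw$midpoint_C) < 0))
  sw0 <- centile_sweep(oxygen_model(14, 0, 14.4, n_cells = 100),
                       c(10, 15, 20))
  expect_true(all(abs(sw0$midpoint_C - 14) < 1e-8))
})

test_that("inhibition fractions interpolate the sweep over the tissue distribution", {
  # no inhibition anywhere -> zero fractions
  sw1 <- data.frame(centile = c(50, 70, 95),
                    inhibition = c(0, 0, 0))
  expect_equal(unname(inhibition_fractions(sw1, 0.1)), 0)
  # step inhibition beyond the 80th centile, threshold 10% -> 20% of tissue
  sw2 <- data.frame(centile = c(50, 60, 70, 80, 80.0001, 95),
                    inhibition = c(0, 0, 0, 0, 0.5, 0.5))
  expect_equal(unname(inhibition_fractions(sw2, 0.10)), 0.2,
               tolerance = 1e-3)
  # brute-force voxelwise oracle: tissue at centile p experiences the
  # interpolated inhibition; count voxels above threshold directly
  set.seed(11)
  m <- oxygen_model(14, 2, 14.4, n_cells = 120)
  cents <- c(50, 60, 70, 80, 90, 95)
  dists <- stats::qgamma(cents / 100, shape = 2, scale = 4)
  sw <- centile_sweep(m, 2 * dists, centiles = cents)
  fr <- inhibition_fractions(sw, c(0.10, 0.20))
  vox <- stats::rgamma(20000, shape = 2, scale = 4)  # tissue distances
  pvox <- stats::ecdf(vox)(vox) * 100
  inh_at <- stats::approx(sw$centile, cummax(sw$inhibition), xout = pvox,
                          rule = 2)$y
  oracle <- c(mean(inh_at >= 0.10), mean(inh_at >= 0.20))
  expect_equal(unname(fr), oracle, tolerance = 0.02)
})
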