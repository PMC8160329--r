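# Calcium event detection, vessel response classification, shuffled null
# and the coupling index.

test_that("global and baseline normalizations follow their definitions", {
  expect_equal(normalize_global(c(0, 5, 10)), c(0, 0.5, 1))
  x <- rnorm(50)
  expect_equal(normalize_global(3 * x + 7), normalize_global(x))
  expect_equal(range(normalize_global(x)), c(0, 1))
  expect_error(normalize_global(rep(2, 10)))
  # baseline mean 2, peak 4 -> dF/F 1; negative baseline uses |F0|
  w <- c(rep(2, 10), 4)
  expect_equal(normalize_baseline(w, 1:10)[11], 1)
  w2 <- c(rep(-2, 10), -1)
  expect_equal(normalize_baseline(w2, 1:10)[11], 0.5)
  expect_warning(out <- normalize_baseline(c(rep(0, 5), 1), 1:5))
  expect_null(out)
})

test_that("event detection finds synthetic transients at the right times", {
  rate <- 10
  tt <- seq(0, 40, by = 1 / rate)
  set.seed(2)
  noise <- rnorm(length(tt), sd = 0.005)
  kern <- function(t0) ifelse(tt >= t0, exp(-(tt - t0) / 0.4), 0)
  # noise has no preferred scale after min-max normalization, so the
  # detector fires on it at a low chance rate; real transients dominate
  f <- 1 + noise
  n_noise <- nrow(detect_calcium_events(f, rate))
  expect_lt(n_noise / 40, 0.25)   # sparse chance events per second
  f1 <- 1 + 0.5 * kern(12) + noise
  ev1 <- detect_calcium_events(f1, rate)
  expect_equal(nrow(ev1), 1)      # the transient suppresses noise peaks
  expect_lt(abs(ev1$time - 12), 1 / rate + 1e-9)
  # two transients 2 s apart resolved separately
  f2 <- 1 + 0.5 * kern(12) + 0.5 * kern(14) + 0.4 * kern(25) + noise
  ev2 <- detect_calcium_events(f2, rate)
  expect_equal(nrow(ev2), 3)
  expect_true(all(abs(sort(ev2$time) - c(12, 14, 25)) <= 1 / rate + 1e-9))
  # count invariant under affine rescaling of the raw trace
  ev3 <- detect_calcium_events(10 + 4 * f2, rate)
  expect_equal(nrow(ev3), nrow(ev2))
  expect_equal(ev3$time, ev2$time)
  # peaks too close to the edges are dropped
  f4 <- 1 + 0.5 * kern(2) + noise
  expect_equal(nrow(detect_calcium_events(f4, rate)), 0)
})

test_that("response classification applies the duration and amplitude rules", {
  rate <- 10
  nb <- 5 * rate
  n <- nb + 10 * rate + 1
  set.seed(3)
  base <- 5 + rnorm(n, sd = 0.05)
  # flat -> not responsive
  r0 <- classify_response(base, rate)
  expect_false(r0$responsive)
  # +2 SD step for 1 s starting +2 s -> responsive with latency 2 s
  d <- base
  sdb <- stats::sd((base[1:nb] - mean(base[1:nb])) / mean(base[1:nb]))
  step_idx <- (nb + 1 + 2 * rate):(nb + 3 * rate)
  d[step_idx] <- d[step_idx] + 2.5 * sdb * mean(base[1:nb])
  r1 <- classify_response(d, rate)
  expect_true(r1$responsive)
  expect_equal(r1$latency, 2, tolerance = 0.2 / 2)
  # same amplitude but 0.4 s -> too short
  d2 <- base
  blip <- (nb + 1 + 2 * rate):(nb + 1 + 2 * rate + 3)
  d2[blip] <- d2[blip] + 2.5 * sdb * mean(base[1:nb])
  expect_false(classify_response(d2, rate)$responsive)
  # missing data invalidates the record
  d3 <- base; d3[1:40] <- NA
  expect_false(classify_response(d3, rate)$valid)
})

test_that("shuffled null matches a Monte-Carlo oracle of the same rule on white noise", {
  rate <- 10
  set.seed(4)
  d <- rnorm(1200)
  events <- c(20, 40, 60, 80, 100)
  r1 <- shuffled_null(d, rate, events, n_iter = 60, seed = 9)
  r2 <- shuffled_null(d, rate, events, n_iter = 60, seed = 9)
  expect_identical(r1, r2)  # seeded determinism
  # independent brute-force oracle: apply the rule to fresh Gaussian
  # windows (permuted white noise is exchangeable with fresh draws)
  nb <- 5 * rate; np <- 10 * rate
  mc <- replicate(3000, {
    w <- rnorm(nb + np + 1, mean = 10, sd = 0.5)
    b <- w[1:nb]
    f0 <- mean(b)
    norm <- (w - f0) / abs(f0)
    thr <- mean(norm[1:nb]) + stats::sd(norm[1:nb])
    above <- norm[(nb + 2):(nb + 1 + 5 * rate)] > thr
    r <- rle(above)
    any(r$values & r$lengths > 0.5 * rate)
  })
  p_mc <- mean(mc)
  n_cls <- attr(r1, "n")
  ci <- p_mc + c(-1, 1) * 1.96 * sqrt(p_mc * (1 - p_mc) / n_cls)
  expect_gt(as.numeric(r1), ci[1])
  expect_lt(as.numeric(r1), ci[2])
})

test_that("genuinely locked responses beat their shuffled null", {
  rate <- 10
  set.seed(5)
  n <- 1500
  d <- 5 + rnorm(n, sd = 0.02)
  events <- seq(20, 130, by = 15)
  for (t0 in events) {
    idx <- round(t0 * rate) + seq_len(2 * rate)
    d[idx] <- d[idx] + 0.5
  }
  aligned <- mean(vapply(events, function(t0) {
    i <- round(t0 * rate) + 1
    classify_response(d[(i - 5 * rate):(i + 10 * rate)], rate)$responsive
  }, logical(1)))
  null_rate <- shuffled_null(d, rate, events, n_iter = 40, seed = 1)
  expect_equal(aligned, 1)
  expect_lt(as.numeric(null_rate), 0.5)
})

test_that("the coupling index is the dilation/calcium ratio and scale-free", {
  expect_equal(nvc_index(0.05, 0.5), 0.1)
  expect_equal(nvc_index(0.05, 1.0), 0.05)
  expect_equal(nvc_index(3 * 0.05, 3 * 0.5), nvc_index(0.05, 0.5))
  expect_true(is.na(nvc_index(0.05, 0)))
  expect_true(is.na(nvc_index(0.05, -1)))
})

test_that("ROI correlations recover shared signal fractions", {
  set.seed(6)
  n <- 4000
  shared <- rnorm(n)
  rho <- 0.6
  traces <- sapply(1:5, function(i)
    sqrt(rho) * shared + sqrt(1 - rho) * rnorm(n))
  rc <- roi_pairwise_correlation(traces)
  expect_equal(dim(rc$R), c(5, 5))
  expect_true(all(diag(rc$R) == 1))
  expect_equal(rc$mean_offdiag, rho, tolerance = 0.1)
  # independent noise decorrelates
  ind <- sapply(1:4, function(i) rnorm(n))
  expect_lt(abs(roi_pairwise_correlation(ind)$mean_offdiag), 2 / sqrt(n) * 3)
  # constant ROI excluded
  bad <- cbind(traces[, 1:2], rep(1, n))
  rcb <- roi_pairwise_correlation(bad)
  expect_true(all(is.na(rcb$R[3, 1:2])))
})

test_that("Holm-Bonferroni equals the step-down oracle", {
  expect_equal(holm_bonferroni(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_bonferroni(0.03), 0.03)
  set.seed(7)
  for (i in 1:1000) {
    m <- sample(1:12, 1)
    p <- runif(m)
    expect_equal(holm_bonferroni(p), stats::p.adjust(p, method = "holm"))
  }
  expect_error(holm_bonferroni(c(0.5, 1.2)))
})
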