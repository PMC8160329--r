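# Derived haemodynamic channels, rest segmentation and metabolic events.

test_that("derived channels follow their defining identities", {
  h <- make_hemo(duration = 20, seed = 1)
  h$data$flux <- rep(2, nrow(h$data))
  h$data$HbO <- rep(1, nrow(h$data))
  h$data$Hbr <- rep(1, nrow(h$data))
  h <- derive_channels(h)
  expect_equal(h$data$Hbt[1], 2)
  expect_equal(h$data$SO2[1], 50)
  expect_equal(h$data$CMRO2[1], 1)
  # SO2 + 100 Hbr/Hbt = 100 wherever defined
  h2 <- derive_channels(make_hemo(duration = 30, noise_sd = 0.05,
                                  seed = 2))
  with(h2$data, expect_equal(SO2 + 100 * Hbr / Hbt, rep(100, length(SO2))))
  # CMRO2 linear in CBF, invariant to common rescaling of HbO/Hbr
  h3 <- h2; h3$data$flux <- 3 * h3$data$flux
  h3 <- derive_channels(h3)
  expect_equal(h3$data$CMRO2, 3 * h2$data$CMRO2)
  h4 <- h2; h4$data$HbO <- 5 * h4$data$HbO; h4$data$Hbr <- 5 * h4$data$Hbr
  h4 <- derive_channels(h4)
  expect_equal(h4$data$CMRO2, h2$data$CMRO2)
  # zero Hbt -> missing CMRO2
  h5 <- h2; h5$data$HbO[1] <- 0; h5$data$Hbr[1] <- 0
  h5 <- derive_channels(h5)
  expect_true(is.na(h5$data$CMRO2[1]))
})

test_that("rest segmentation masks bouts with padding", {
  h <- make_hemo(duration = 60, locomotion_bouts = list(c(20, 10)),
                 seed = 1)
  m0 <- segment_rest(h, pad = 0)
  expect_equal(sum(!m0) / h$rate, 10, tolerance = 0.01)
  m2 <- segment_rest(h, pad = 2)
  expect_equal(sum(!m2) / h$rate, 14, tolerance = 0.01)
  hd <- make_hemo(duration = 30, seed = 2)
  expect_true(all(segment_rest(hd)))
})

test_that("baseline summaries aggregate sessions into animal means", {
  h1 <- make_hemo(duration = 30, baselines = list(CBF = 100, HbO = 60,
                                                  Hbr = 40), seed = 1)
  h2 <- make_hemo(duration = 30, baselines = list(CBF = 300, HbO = 60,
                                                  Hbr = 40), seed = 2)
  h1 <- derive_channels(h1); h2 <- derive_channels(h2)
  out <- baseline_summary(list(h1, h2), list(segment_rest(h1),
                                             segment_rest(h2)),
                          animal = c("a", "a"))
  expect_equal(nrow(out), 1)
  expect_equal(out$flux, 200)
  expect_error(baseline_summary(list(h1), list(rep(FALSE, 1200)), "a"))
  # noisy truth baselines recovered within the standard error
  hn <- derive_channels(make_hemo(duration = 120, noise_sd = 0.05,
                                  seed = 3))
  bn <- baseline_summary(list(hn), list(segment_rest(hn)), "a")
  se <- 0.05 * 100 / sqrt(120 * 40)
  expect_lt(abs(bn$flux - 100), 5 * se)
})

test_that("metabolic events recover injected gains and times", {
  ev_times <- c(30, 70, 110, 150)
  g <- 0.3; nvcg <- 0.4
  h <- make_hemo(duration = 200, event_times = ev_times, event_gain = g,
                 nvc_gain = nvcg, noise_sd = 0, seed = 4)
  h <- derive_channels(h)
  me <- detect_metabolic_events(h)
  expect_equal(nrow(me), length(ev_times))
  # peak lands at the kernel maximum, one kernel-peak time after onset
  expect_true(all(abs(me$time - (ev_times + 1)) <= 1 / h$rate + 1e-9))
  # forward-model oracle for the dF/F amplitude: the 5 s baseline before
  # the peak includes part of the event rise
  tt <- h$data$t
  kern <- pmax(0, tt - ev_times[1]); kern <- kern * exp(1 - kern)
  pk <- which.max(kern)
  base <- mean(kern[(pk - 5 * h$rate):(pk - 1)])
  expected_dff <- g * (kern[pk] - base) / (1 + g * base)
  expect_equal(me$cmro2_peak[1], expected_dff, tolerance = 1e-6)
  # flat CMRO2 cannot be normalized into events
  h0 <- derive_channels(make_hemo(duration = 60, noise_sd = 0, seed = 5))
  expect_error(detect_metabolic_events(h0))
})

test_that("regional coupling index recovers the generator's gain in both conventions", {
  gains <- c(0.2, 0.35, 0.5)
  med <- vapply(gains, function(gg) {
    h <- derive_channels(make_hemo(duration = 200,
                                   event_times = c(30, 80, 130),
                                   event_gain = 0.3, nvc_gain = gg,
                                   noise_sd = 0, seed = 6))
    stats::median(detect_metabolic_events(h)$nvc_index)
  }, numeric(1))
  expect_true(all(diff(med) > 0))           # monotone in the true gain
  expect_equal(med, gains, tolerance = 0.1)  # approximately recovered
  expect_equal(regional_nvc_index(0.02, 0.1), 0.2)
  expect_equal(regional_nvc_index(0, 0.1), 0)
  expect_equal(regional_nvc_index(0.02, 0.1,
                                  direction = "cmro2_over_hbt"), 5)
  expect_true(is.na(regional_nvc_index(0.02, -0.1)))
})

test_that("calcium and CMRO2 events share one detection path", {
  # feeding the CMRO2 channel through the calcium detector directly gives
  # the same events the metabolic wrapper reports
  h <- derive_channels(make_hemo(duration = 150,
                                 event_times = c(30, 75, 120),
                                 event_gain = 0.3, noise_sd = 0,
                                 seed = 7))
  me <- detect_metabolic_events(h)
  ev <- detect_calcium_events(h$data$CMRO2, h$rate)
  expect_equal(me$time, ev$time)
  expect_equal(me$cmro2_peak, ev$peak_dff)
})
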