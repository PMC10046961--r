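test_that("smoothing is mean-preserving with the documented edge behaviour", {
  const <- new_trace(rep(7.5, 40), 2)
  expect_equal(smooth_trace(const, 2.5)$values, rep(7.5, 40))

  # single-sample spike of height h with a w-sample window: interior plateau h/w
  spike <- new_trace(c(rep(0, 20), 10, rep(0, 20)), 2)
  smv <- smooth_trace(spike, 2.5)$values   # w = 5 samples
  expect_equal(smv[19:23], rep(10 / 5, 5))
  expect_equal(smv[10], 0)

  # affine signals pass through on the interior
  ramp <- new_trace(3 + 2 * seq(0, 19.5, by = 0.5), 2)
  expect_equal(smooth_trace(ramp, 2.5)$values[3:38], ramp$values[3:38])

  set.seed(4)
  noisy <- new_trace(rnorm(500, 100, 5), 2)
  sm <- smooth_trace(noisy, 2.5)
  expect_lt(abs(mean(sm$values) - mean(noisy$values)) / abs(mean(noisy$values)),
            1e-9)

  expect_error(smooth_trace(noisy, 0.4), "2 sampling intervals")
})

test_that("differentiation matches closed forms", {
  expect_equal(differentiate_trace(new_trace(rep(2, 30), 2)), rep(0, 30))

  ramp <- new_trace(3 * seq(0, 14.5, by = 0.5), 2)
  expect_equal(differentiate_trace(ramp), rep(3, 30))

  # sine: derivative amplitude = omega * A within discretization error
  f <- 0.05; A <- 4; omega <- 2 * pi * f
  tt <- seq(0, 100, by = 0.1)
  sine <- new_trace(A * sin(omega * tt), 10)
  d <- differentiate_trace(sine)
  expect_lt(abs(max(d[5:995]) - omega * A) / (omega * A), 0.01)

  expect_error(differentiate_trace(new_trace(c(1, 2), 2)), "3 samples")
})

test_that("detector finds constructed pulses and merges within refractory", {
  # 12 events at SNR 20, uniform spread
  onsets <- seq(40, 1150, length.out = 12)
  tr <- make_kernel_trace(onsets, rep(100, 12), duration = 1200,
                          noise_sd = 5, seed = 21)
  ev <- detect_pulses(tr)
  large <- ev[ev$is_large, ]
  expect_equal(nrow(large), 12L)
  expect_true(all(abs(sort(large$top_time) - (onsets + 2)) <= 1))
  expect_true(all(large$bottom_time < large$top_time))
  expect_true(all(large$top_time <= large$end_time))

  # pulses 3 s apart resolve; 1 s apart merge (refractory 2 s). The kernel
  # must be sharp enough that the inter-pulse dip survives the 2.5 s
  # smoothing window (see the resolution-limit note in the vignette).
  two_far <- make_kernel_trace(c(40, 43), c(100, 100), rise = 1, tau = 1.5,
                               duration = 120, noise_sd = 2, seed = 22)
  expect_equal(nrow(detect_pulses(two_far)), 2L)
  two_close <- make_kernel_trace(c(40, 41), c(100, 100), rise = 1, tau = 1.5,
                                 duration = 120, noise_sd = 2, seed = 22)
  expect_equal(nrow(detect_pulses(two_close)), 1L)

  # pure noise: no large events
  for (s in 1:3) {
    flat <- make_kernel_trace(numeric(0), numeric(0), duration = 1200,
                              noise_sd = 5, seed = s)
    ev0 <- detect_pulses(flat)
    expect_equal(sum(ev0$is_large), 0L)
  }
})

test_that("detection is scale-equivariant and rate-robust", {
  onsets <- c(50, 150, 300, 420, 600, 790, 950, 1100)
  tr <- make_kernel_trace(onsets, runif(8, 80, 120), duration = 1200,
                          noise_sd = 4, seed = 31)
  ev1 <- detect_pulses(tr)
  c0 <- 7.3
  tr2 <- tr
  tr2$values <- tr$values * c0
  ev2 <- detect_pulses(tr2)
  expect_equal(nrow(ev2), nrow(ev1))
  expect_identical(ev2$is_large, ev1$is_large)
  expect_equal(ev2$top_time, ev1$top_time)
  expect_equal(ev2$width_return, ev1$width_return)
  expect_equal(ev2$amplitude, c0 * ev1$amplitude, tolerance = 1e-9)
  expect_equal(ev2$auc, c0 * ev1$auc, tolerance = 1e-9)

  f1 <- compute_features(tr, ev1)
  f2 <- compute_features(tr2, ev2)
  expect_equal(f2$peak_number, f1$peak_number)
  expect_equal(f2$mean_width, f1$mean_width)
  expect_equal(f2$mean_peak_to_peak, f1$mean_peak_to_peak)
  expect_equal(f2$mean_amplitude, c0 * f1$mean_amplitude, tolerance = 1e-9)

  # same noise-free signal at 2 Hz and 10 Hz: identical peak number
  for (rz in c(2, 10)) {
    trz <- make_kernel_trace(onsets, rep(100, 8), duration = 1200,
                             rate_hz = rz)
    fz <- compute_features(trz, detect_pulses(trz))
    expect_equal(fz$peak_number, 4)   # 8 pulses / 20 min
  }
})

test_that("raising the derivative threshold never adds events", {
  sim <- simulate_well(well_model(base_rate = 18), seed = 5)
  counts <- vapply(c(2, 3, 5, 8, 12, 20, 50), function(k)
    nrow(detect_pulses(sim$trace, detector_config(threshold_k = k))),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("background estimation recovers baseline and drift", {
  tr <- make_kernel_trace(numeric(0), numeric(0), duration = 600,
                          noise_sd = 3, seed = 41)
  expect_equal(estimate_background(tr, NULL), smooth_trace(tr, 2.5)$values)

  onsets <- c(60, 200, 350, 480)
  for (drift in c(0, 0.05)) {
    trp <- make_kernel_trace(onsets, rep(100, 4), duration = 600,
                             baseline = 200, drift = drift, noise_sd = 3,
                             seed = 42)
    ev <- detect_pulses(trp)
    bg <- estimate_background(trp, ev)
    truth_bg <- 200 + drift * trp$times
    expect_lt(max(abs(bg - truth_bg)), 3 * 3)
  }

  # events covering the whole trace leave no background support
  ev_all <- data.frame(bottom_time = 0, top_time = 10, end_time = 599.5,
                       amplitude = 1, width_rise = 1, width_return = 1,
                       auc = 1, is_large = TRUE)
  expect_error(estimate_background(tr, ev_all), "background support")
})

test_that("waveform features follow their arithmetic definitions", {
  onsets <- seq(40, 1150, length.out = 12)
  tr <- make_kernel_trace(onsets, rep(100, 12), duration = 1200,
                          noise_sd = 2, seed = 51)
  ev <- detect_pulses(tr)
  ft <- compute_features(tr, ev)
  expect_equal(ft$peak_number, 6)   # 12 large events / 20 min

  ev2 <- ev[1:2, ]
  ev2$top_time <- c(100, 160)
  ev2$is_large <- TRUE
  expect_equal(compute_features(tr, ev2)$mean_peak_to_peak, 60000)

  # single kernel pulse: amplitude within 5% of A, auc within 10% of the
  # kernel integral up to the 90% return point (numerical oracle)
  A <- 150
  tr1 <- make_kernel_trace(100, A, duration = 300, baseline = 50)
  ev1 <- detect_pulses(tr1)
  expect_equal(nrow(ev1), 1L)
  ft1 <- compute_features(tr1, ev1)
  expect_lt(abs(ft1$mean_amplitude - A) / A, 0.05)
  t_end <- 2 + 8 * log(10)            # decay reaches 10% of A
  fine <- seq(0, t_end, by = 0.001)
  kern <- ifelse(fine <= 2, A * fine / 2, A * exp(-(fine - 2) / 8))
  oracle_auc <- sum(kern) * 0.001
  expect_lt(abs(ft1$mean_auc - oracle_auc) / oracle_auc, 0.10)

  # degenerate well: zero large events
  flat <- make_kernel_trace(numeric(0), numeric(0), duration = 600,
                            noise_sd = 2, seed = 52)
  ft0 <- compute_features(flat, detect_pulses(flat))
  expect_equal(ft0$peak_number, 0)
  expect_true(is.na(ft0$mean_amplitude) && is.na(ft0$mean_width) &&
                is.na(ft0$mean_auc) && is.na(ft0$mean_peak_to_peak))
})

test_that("simulated ground truth is recovered at high SNR", {
  # mirrors the detection-quality contract on a small scale (the full
  # 200-well sweep runs in the acceptance suite)
  total_truth <- total_det <- total_match <- 0
  for (s in 1:20) {
    sim <- simulate_well(well_model(base_rate = 5 + (s %% 4) * 5), seed = 600 + s)
    ev <- detect_pulses(sim$trace)
    m <- match_events(sim$truth$peak_time, ev$top_time[ev$is_large])
    total_truth <- total_truth + nrow(sim$truth)
    total_det <- total_det + sum(ev$is_large)
    total_match <- total_match + m$n_matched
  }
  expect_gte(total_match / total_truth, 0.95)
  expect_gte(total_match / total_det, 0.95)
})
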