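amp_of <- function(y, freq, fs) {
  # least-squares amplitude of a sinusoid, interior samples only
  n <- length(y)
  keep <- seq(round(n / 5), round(4 * n / 5))
  t <- (keep - 1) / fs
  fit <- lm(y[keep] ~ sin(2 * pi * freq * t) + cos(2 * pi * freq * t))
  sqrt(sum(coef(fit)[2:3]^2))
}

test_that("low-pass filter has unit DC gain, passes 1 Hz, rejects 30 Hz", {
  fs <- 100
  const <- signal_channel("x", rep(5, 3000), kind = "other")
  fc <- lowpass_filter(const, 6, fs)
  expect_lt(max(abs(fc$samples[1000:2000] - 5)), 1e-9)

  t <- (0:2999) / fs
  lo <- lowpass_filter(signal_channel("x", sin(2 * pi * 1 * t),
                                      kind = "other"), 6, fs)
  expect_lt(abs(amp_of(lo$samples, 1, fs) - 1), 0.01)

  hi <- lowpass_filter(signal_channel("x", sin(2 * pi * 30 * t),
                                      kind = "other"), 6, fs)
  expect_lt(amp_of(hi$samples, 30, fs), 0.05)

  expect_error(lowpass_filter(const, 60, fs), "Nyquist")
  expect_error(lowpass_filter(signal_channel("x", rep(1, 10),
                                             kind = "other"), 6, fs),
               "too short")
})

test_that("heel strikes are upward threshold crossings, debounced", {
  fs <- 100
  flat <- signal_channel("grf_vy_r", rep(500, 200))
  ev <- detect_heel_strikes(flat, fs)
  expect_length(ev$heel_strike_times, 0L)

  # square wave: 0.4 s at 0 N then 0.7 s at 700 N, repeated
  cyc <- c(rep(0, 40), rep(700, 70))
  sq <- signal_channel("grf_vy_r", rep(cyc, 6))
  ev <- detect_heel_strikes(sq, fs)
  true_edges <- (seq_len(6) - 1) * 1.1 + 0.40
  expect_length(ev$heel_strike_times, 6L)
  expect_lt(max(abs(ev$heel_strike_times - true_edges)), 0.01 + 1e-12)

  ang <- signal_channel("ankle_angle_r", rep(cyc, 2))
  expect_error(detect_heel_strikes(ang, fs), "grf_force")
})

test_that("detection recovers generator ground truth within one sample", {
  gen <- generate_gait_trial(quiet_config(n_strides = 8, seed = 5))
  ev <- detect_heel_strikes(gen$trial$channels$grf_vy_r, 100)
  expect_length(ev$heel_strike_times, 9L)
  # detector reports the first at/above sample, i.e. within one sample
  # after the continuous crossing
  dt <- ev$heel_strike_times - gen$truth$heel_strike_times
  expect_true(all(dt >= -1e-12 & dt <= 0.01 + 1e-12))
})

test_that("detection count is unchanged by noise well below threshold", {
  gen <- generate_gait_trial(quiet_config(n_strides = 8, seed = 6))
  clean <- gen$trial$channels$grf_vy_r
  n_clean <- length(detect_heel_strikes(clean, 100)$heel_strike_times)
  for (s in 1:5) {
    set.seed(s)
    noisy <- signal_channel("grf_vy_r",
                            clean$samples + rnorm(length(clean$samples), 0, 3))
    expect_identical(
      length(detect_heel_strikes(noisy, 100)$heel_strike_times), n_clean)
  }
})

test_that("swing-phase samples are zeroed across all GRF components", {
  vy <- signal_channel("grf_vy_r", c(0, 10, 40, 10))
  vx <- signal_channel("grf_vx_r", c(3, -2, 5, 1))
  out <- zero_swing_grf(list(vy, vx), "grf_vy_r")
  expect_equal(out$grf_vy_r$samples, c(0, 0, 40, 0))
  expect_equal(out$grf_vx_r$samples, c(0, 0, 5, 0))   # co-zeroed

  all_stance <- signal_channel("grf_vy_r", c(100, 200, 300))
  out2 <- zero_swing_grf(list(all_stance), "grf_vy_r")
  expect_equal(out2$grf_vy_r$samples, c(100, 200, 300))

  # random input: shear zeroed exactly where vertical is sub-threshold
  set.seed(2)
  v <- abs(rnorm(300, 40, 30))
  sh <- rnorm(300)
  out3 <- zero_swing_grf(list(signal_channel("grf_vy_r", v),
                              signal_channel("grf_vx_r", sh)), "grf_vy_r")
  expect_identical(out3$grf_vx_r$samples == 0, v < 30 | sh == 0)
})

test_that("segmentation indexing, random start, and duration bookkeeping", {
  gen <- generate_gait_trial(quiet_config(n_strides = 6, seed = 3))
  ev <- detect_heel_strikes(gen$trial$channels$grf_vy_r, 100)
  expect_length(ev$heel_strike_index, 7L)

  st <- segment_strides(gen$trial, ev, n_strides = 5, start_index = 0)
  expect_length(st, 5L)
  expect_equal(st[[1L]]$t_start, ev$heel_strike_times[[1L]])
  # durations sum to the span of the used heel strikes
  expect_equal(sum(vapply(st, `[[`, numeric(1), "duration")),
               ev$heel_strike_times[[6L]] - ev$heel_strike_times[[1L]])

  # with exactly n+1 events there is a single valid random start
  ev6 <- ev
  ev6$heel_strike_times <- ev$heel_strike_times[1:6]
  ev6$heel_strike_index <- ev$heel_strike_index[1:6]
  for (s in c(1, 99)) {
    st_r <- segment_strides(gen$trial, ev6, 5, "random", seed = s)
    expect_equal(st_r[[1L]]$t_start, ev6$heel_strike_times[[1L]])
  }
  expect_error(segment_strides(gen$trial, ev6, 6), "6 were detected")
})

test_that("segmented durations match generator stride durations within one sample", {
  cfg <- synthetic_gait_config(n_strides = 10, sigma_period = 0.03,
                               seed = 21)
  gen <- generate_gait_trial(cfg)
  st <- segment_generated(gen, n_strides = 10)
  durs <- vapply(st, `[[`, numeric(1), "duration")
  expect_lt(max(abs(durs - gen$truth$stride_durations)), 0.01 + 1e-12)
})

test_that("filtering commutes with segmentation away from chunk edges", {
  gen <- generate_gait_trial(synthetic_gait_config(n_strides = 9, seed = 8))
  full <- filter_trial(gen$trial)
  ev <- detect_heel_strikes(gen$trial$channels$grf_vy_r, 100)
  st_full <- segment_strides(full, ev, 9, start_index = 0)

  # filter only a chunk spanning strides 2..8, then compare stride 5
  i0 <- ev$heel_strike_index[[2L]]
  i1 <- ev$heel_strike_index[[9L]]
  chunk_ch <- lapply(gen$trial$channels, function(ch)
    signal_channel(ch$name, ch$samples[i0:i1], kind = ch$kind))
  chunk <- gait_trial(chunk_ch, 100)
  chunk_f <- filter_trial(chunk)
  off <- ev$heel_strike_index[[5L]] - i0 + 1L
  len <- ev$heel_strike_index[[6L]] - ev$heel_strike_index[[5L]] + 1L
  for (nm in names(gen$trial$channels)) {
    a <- st_full[[5L]]$channels[[nm]]$samples
    b <- chunk_f$channels[[nm]]$samples[off:(off + len - 1L)]
    expect_lt(max(abs(a - b)), 1e-6)
  }
})
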