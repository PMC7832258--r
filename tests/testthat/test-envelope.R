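test_that("spectrogram framing follows the floor((N - win)/hop) + 1 rule", {
  x <- sin(2 * pi * 5000 * (0:44099) / 44100)
  sp <- compute_spectrogram(x, 44100, window_length = 0.010, hop = 0.0025)
  expect_equal(length(sp$frame_times), floor((44100 - 441) / 110) + 1) # 397
  expect_equal(length(sp$frame_times), 397)
  # pure tone: time-averaged power peaks at the bin nearest 5 kHz
  avg <- colMeans(sp$power)
  expect_equal(sp$frequency_bins[which.max(avg)], 5000, tolerance = 0.02)
})

test_that("all-zero audio yields an all-zero, fully masked spectrogram trace", {
  sp <- compute_spectrogram(numeric(44100), 44100)
  expect_true(all(sp$power == 0))
  tr <- trace_max_frequency(sp)
  expect_true(all(tr$frequency_hz == 0))
  expect_true(all(!tr$quality))
})

test_that("audio shorter than one analysis window is refused", {
  expect_error(compute_spectrogram(numeric(100), 44100),
               class = "dopplervti_error_input")
})

test_that("the percentile tracer matches a brute-force cumulative-sum oracle", {
  # hand-built frame: uniform power on bins 0..5000 Hz, zero above
  bins <- seq(0, 10000, by = 50)
  p <- as.numeric(bins <= 5000)
  spec <- structure(list(
    frame_times = 0, frequency_bins = bins,
    power = matrix(p, nrow = 1), window_length = 0.01, hop = 0.0025,
    sample_rate = 20000), class = "doppler_spectrogram")
  tr <- trace_max_frequency(spec, percentile = 0.95, smooth_frames = 1)
  # oracle: first bin where cumsum >= 0.95 * total
  oracle <- bins[which(cumsum(p) >= 0.95 * sum(p))[1]]
  expect_equal(tr$frequency_hz, oracle)
  expect_equal(oracle, 4750)

  # flat all-noise frame: nothing above its own floor -> masked zero
  spec$power <- matrix(rep(1, length(bins)), nrow = 1)
  tr2 <- trace_max_frequency(spec, smooth_frames = 1)
  expect_equal(tr2$frequency_hz, 0)
  expect_false(tr2$quality)
})

test_that("raising the percentile never lowers the traced frequency", {
  au <- synthesize_audio(slow_envelope(3), snr_db = 20, seed = 12)
  sp <- compute_spectrogram(au$samples[, 1], 44100)
  prev <- rep(-Inf, length(sp$frame_times))
  for (q in c(0.5, 0.8, 0.9, 0.95, 0.99)) {
    tr <- trace_max_frequency(sp, percentile = q, smooth_frames = 1)
    expect_true(all(tr$frequency_hz >= prev - 1e-9))
    prev <- tr$frequency_hz
  }
})

test_that("a noiseless single tone is traced within one frequency bin", {
  x <- sin(2 * pi * 5000 * (0:88199) / 44100)
  tr <- trace_max_frequency(compute_spectrogram(x, 44100))
  bin_width <- 44100 / 441
  expect_true(all(abs(tr$frequency_hz[tr$quality] - 5000) <= bin_width))
})

test_that("trace_envelope recovers a known slowly varying envelope", {
  env <- slow_envelope(8)
  au <- synthesize_audio(env, snr_db = Inf, seed = 7)
  tr <- trace_envelope(au, channel = 1)
  tru <- stats::approx(env$time_s, env$velocity_cm_s, xout = tr$time_s)$y
  err <- tr$velocity_cm_s - tru
  expect_gt(mean(abs(err[tr$quality]) <= one_bin_cm_s()), 0.98)
})
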