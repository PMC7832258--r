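test_that("per-beat true VTI is self-consistent with the envelope integral", {
  truth <- make_velocity_track(valsalva_preset("responder", jitter = TRUE,
                                               seed = 9), seed = 9)
  for (ch in c("carotid", "aortic")) {
    env <- truth$envelope[[ch]]
    beats <- truth$beats[[ch]]
    # integral over the half-open beat interval on the native grid,
    # recomputed from scratch with cumulative trapezoid weights
    dt <- diff(env$time_s)
    seg <- (env$velocity_cm_s[-1] + env$velocity_cm_s[-nrow(env)]) / 2 * dt
    cumint <- c(0, cumsum(seg))
    recomputed <- vapply(seq_len(nrow(beats)), function(i) {
      a <- beats$onset_s[i]
      b <- a + beats$rr_s[i]
      idx <- which(env$time_s >= a & env$time_s < b)
      hi <- min(max(idx) + 1L, nrow(env))
      cumint[hi] - cumint[min(idx)]
    }, numeric(1))
    expect_true(all(abs(recomputed - beats$vti_cm) / beats$vti_cm < 1e-3))
  }
})

test_that("an identity profile yields identical beats and zero window change", {
  truth <- make_velocity_track(valsalva_preset("identity"), seed = 4)
  vti <- truth$beats$carotid$vti_cm
  # beats are identical up to 5-ms grid quantization of the onset phase
  expect_lt(diff(range(vti)) / mean(vti), 0.01)
  w <- analyze_truth(truth)
  ch <- subject_changes(w)
  expect_equal(ch$t1_t2_pct[ch$metric == "carotid_vti"], 0, tolerance = 0.01)
})

test_that("track generation and audio synthesis are deterministic under a fixed seed", {
  p <- valsalva_preset("responder", jitter = TRUE, seed = 5)
  t1 <- make_velocity_track(p, seed = 11)
  t2 <- make_velocity_track(p, seed = 11)
  expect_identical(t1$envelope$carotid, t2$envelope$carotid)
  short <- slow_envelope(3)
  a1 <- synthesize_audio(short, snr_db = 20, seed = 8)
  a2 <- synthesize_audio(short, snr_db = 20, seed = 8)
  expect_identical(a1$samples, a2$samples) # bitwise
  a3 <- synthesize_audio(short, snr_db = 20, seed = 9)
  expect_false(identical(a1$samples, a3$samples))
})

test_that("a zero-velocity envelope synthesizes silence", {
  env <- tibble::tibble(time_s = seq(0, 1, 1 / 200),
                        velocity_cm_s = 0)
  au <- synthesize_audio(env, snr_db = Inf, seed = 1)
  expect_true(all(au$samples == 0))
})

test_that("Nyquist violations are refused", {
  env <- tibble::tibble(time_s = seq(0, 1, 1 / 200), velocity_cm_s = 100)
  cfg <- doppler_config(audio_sample_rate_hz = 8000)
  expect_error(synthesize_audio(env, cfg, seed = 1),
               class = "dopplervti_error_config")
})

test_that("constant-velocity audio has its spectral edge at the Doppler shift", {
  env <- tibble::tibble(time_s = seq(0, 2, 1 / 200), velocity_cm_s = 100)
  au <- synthesize_audio(env, snr_db = Inf, seed = 6)
  tr <- trace_max_frequency(compute_spectrogram(au$samples[, 1], 44100))
  edge <- median(tr$frequency_hz[tr$quality])
  expect_equal(edge, 2 * 4e6 * 1.0 / 1540, tolerance = 0.03)
})

test_that("the monitor channel reports the programmed SV and MAP plateaus", {
  p <- valsalva_preset("responder", jitter = FALSE)
  sv <- simulate_sv_channel(p)
  expect_equal(sv$time_s, c(0, 20, 40, 60)) # 20-s cadence from t = 0
  w <- sv_windows(sv, 60)
  expect_equal(percent_change(w$sv_ml[1], w$sv_ml[2]), -26, tolerance = 1e-6)
  expect_equal(percent_change(w$map_mmhg[1], w$map_mmhg[2]), 4,
               tolerance = 1e-6)
  id <- simulate_sv_channel(valsalva_preset("identity"))
  expect_true(all(id$sv_ml == id$sv_ml[1]))
})

test_that("cohort composition, labels, and reproducibility hold by construction", {
  co1 <- simulate_cohort(3, 3, seed = 42)
  co2 <- simulate_cohort(3, 3, seed = 42)
  expect_identical(co1$truth[[2]]$envelope$aortic,
                   co2$truth[[2]]$envelope$aortic)
  expect_equal(co1$group, rep(c("responder", "control"), each = 3))
  # responders programmed well past a 10% aortic fall, shams within it
  ao_hold <- vapply(co1$profile,
                    function(p) p$aortic_hold_vti_multiplier, numeric(1))
  expect_true(all(ao_hold[1:3] < 0.9))
  expect_true(all(abs(ao_hold[4:6] - 1) < 0.1))
  co3 <- simulate_cohort(3, 3, seed = 43)
  expect_false(identical(co1$truth[[1]]$beats$carotid,
                         co3$truth[[1]]$beats$carotid))
})
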