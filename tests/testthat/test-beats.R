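test_that("a clean periodic envelope at 60 bpm yields one onset per second", {
  env <- periodic_envelope(hr_bpm = 60, duration = 10)
  onsets <- detect_beats(env)
  expect_equal(length(onsets), 10, tolerance = 1)
  rr <- diff(onsets)
  expect_true(all(abs(rr - 1) < 0.01))
  expect_equal(compute_hr(onsets), rep(60, length(onsets) - 1),
               tolerance = 0.01)
})

test_that("flat or too-short envelopes raise insufficient-signal errors", {
  flat <- tibble::tibble(time_s = seq(0, 5, 0.005), velocity_cm_s = 0)
  expect_error(detect_beats(flat), class = "dopplervti_error_insufficient_signal")
  short <- periodic_envelope(duration = 1.5)
  expect_error(detect_beats(short),
               class = "dopplervti_error_insufficient_signal")
})

test_that("per-beat VTI matches rectangle and half-sine oracles", {
  # constant envelope 50 cm/s with RR = 1 s: VTI = 50 cm exactly
  env <- tibble::tibble(time_s = seq(0, 3, 0.005), velocity_cm_s = 50,
                        quality = TRUE)
  vti <- compute_beat_vti(env, c(0, 1, 2))
  expect_equal(vti$vti_cm, c(50, 50), tolerance = 1e-6)

  # half-sine beats, peak 100 cm/s, duration 0.5 s: VTI = 2*100*0.5/pi
  t <- seq(0, 2 - 0.005, 0.005)
  hs <- tibble::tibble(time_s = t,
                       velocity_cm_s = 100 * abs(sin(pi * (t %% 0.5) / 0.5)),
                       quality = TRUE)
  vti_hs <- compute_beat_vti(hs, seq(0, 2, 0.5))
  expect_equal(vti_hs$vti_cm, rep(2 * 100 * 0.5 / pi, 4), tolerance = 0.01)
})

test_that("VTI is linear in the envelope and invariant to time shifts", {
  env <- periodic_envelope(hr_bpm = 75, duration = 8)
  onsets <- detect_beats(env)
  v1 <- compute_beat_vti(env, onsets)
  env2 <- dplyr::mutate(env, velocity_cm_s = 2 * velocity_cm_s)
  v2 <- compute_beat_vti(env2, onsets)
  expect_equal(v2$vti_cm, 2 * v1$vti_cm, tolerance = 1e-9)

  shifted <- dplyr::mutate(env, time_s = time_s + 100)
  v3 <- compute_beat_vti(shifted, onsets + 100)
  expect_equal(v3$vti_cm, v1$vti_cm, tolerance = 1e-9)
})

test_that("summed per-beat VTIs conserve the envelope integral between onsets", {
  env <- periodic_envelope(hr_bpm = 68, duration = 10)
  onsets <- detect_beats(env)
  beats <- compute_beat_vti(env, onsets)
  sel <- env$time_s >= onsets[1] & env$time_s <= onsets[length(onsets)]
  whole <- pracma::trapz(env$time_s[sel], env$velocity_cm_s[sel])
  expect_equal(sum(beats$vti_cm), whole, tolerance = 0.01)
})

test_that("beats overlapping masked frames are excluded, not silently kept", {
  env <- periodic_envelope(hr_bpm = 60, duration = 6)
  env$quality[env$time_s >= 2.2 & env$time_s <= 2.4] <- FALSE
  onsets <- detect_beats(env)
  beats <- compute_beat_vti(env, onsets)
  bad <- beats$onset_s < 2.4 & (beats$onset_s + beats$duration_s) > 2.2
  expect_true(all(!beats$kept[bad]))
  expect_true(all(beats$kept[!bad]))
  expect_equal(attr(beats, "dropped"), beats$onset_s[bad])
})

test_that("heart rate computation validates onset ordering", {
  expect_equal(compute_hr(c(0, 0.5)), 120)
  expect_error(compute_hr(c(0, 1, 0.5)), class = "dopplervti_error_input")
  expect_error(compute_hr(2), class = "dopplervti_error_input")
})

test_that("simulator beats are recovered through the traced envelope at SNR 20", {
  fx <- responder_traced()
  bt <- beat_table(fx$env)
  tb <- fx$truth$beats$carotid
  offs <- vapply(tb$onset_s,
                 function(o) min(abs(bt$onset_s - o)), numeric(1))
  expect_gte(mean(offs <= 0.05), 0.95)
  # matched per-beat VTI errors stay small
  idx <- vapply(tb$onset_s,
                function(o) which.min(abs(bt$onset_s - o)), integer(1))
  ok <- offs <= 0.05
  rel <- abs(bt$vti_cm[idx[ok]] - tb$vti_cm[ok]) / tb$vti_cm[ok]
  expect_lte(stats::quantile(rel, 0.9), 0.05)
  # hold-phase heart rate recovers the programmed multiplier
  hold <- bt$onset_s >= 25 & bt$onset_s < 30
  expect_equal(mean(bt$hr_bpm[hold]), 72 * 1.21, tolerance = 0.03)
})

test_that("beats from the noiseless true envelope reproduce true VTI within 1%", {
  truth <- responder_track()
  bt <- beat_table(truth$envelope$carotid)
  tb <- truth$beats$carotid
  idx <- vapply(tb$onset_s,
                function(o) which.min(abs(bt$onset_s - o)), integer(1))
  rel <- abs(bt$vti_cm[idx] - tb$vti_cm) / tb$vti_cm
  expect_lt(max(rel), 0.01)
})
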