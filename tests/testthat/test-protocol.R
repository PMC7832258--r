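test_that("protocol windows follow the terminal-5-second rule", {
  w <- define_windows(c(15, 15, 15, 15))
  expect_equal(w$start_s, c(5, 25, 55))
  expect_equal(w$end_s, c(10, 30, 60))
  w2 <- define_windows(c(10, 10, 10, 10))
  expect_equal(w2$start_s[2:3], c(15, 35))
  expect_equal(w2$end_s[2:3], c(20, 40))
  expect_error(define_windows(c(15, 4, 15, 15)),
               class = "dopplervti_error_config")
})

test_that("window means average kept beats in a half-open interval", {
  beats <- tibble::tibble(onset_s = c(4.9, 5.5, 8, 10), vti_cm = c(99, 20, 22, 99),
                          hr_bpm = c(60, 70, 74, 60), kept = TRUE)
  m <- window_mean(beats, 5, 10)
  expect_equal(m$vti_cm, 21)
  expect_equal(m$hr_bpm, 72)
  expect_equal(m$n_beats, 2)
  single <- window_mean(beats, 7, 9)
  expect_equal(single$vti_cm, 22)
  beats$kept <- c(TRUE, FALSE, FALSE, TRUE)
  expect_error(window_mean(beats, 5, 10),
               class = "dopplervti_error_missing_window")
})

test_that("DSI and SI arithmetic and domain errors behave as defined", {
  expect_equal(compute_dsi(72, 18), 4)
  expect_equal(compute_si(72, 119), 72 / 119)
  expect_equal(compute_si(100, 100), 1)
  # HR x1.21 with VTI x0.77 raises DSI by ~57%
  expect_equal(compute_dsi(72 * 1.21, 18 * 0.77) / compute_dsi(72, 18) - 1,
               1.21 / 0.77 - 1, tolerance = 1e-12)
  expect_equal(compute_dsi(72, 9), 2 * compute_dsi(72, 18))
  expect_error(compute_dsi(72, 0), class = "dopplervti_error_domain")
  expect_error(compute_si(72, -3), class = "dopplervti_error_domain")
})

test_that("percent change matches its convention and reciprocal identity", {
  expect_equal(percent_change(20, 15.4), -23)
  expect_equal(percent_change(10, 21.5), 115)
  expect_equal(percent_change(7, 7), 0)
  expect_error(percent_change(0, 5), class = "dopplervti_error_domain")
  # (1 + p12/100)(1 + p21/100) = 1
  for (ab in list(c(20, 15.4), c(3, 9), c(100, 1))) {
    p1 <- percent_change(ab[1], ab[2])
    p2 <- percent_change(ab[2], ab[1])
    expect_equal((1 + p1 / 100) * (1 + p2 / 100), 1, tolerance = 1e-12)
  }
})

test_that("monitor windowing picks pre-onset, minimum, and final samples", {
  sv <- tibble::tibble(time_s = c(0, 20, 40, 60), sv_ml = c(100, 80, 70, 90),
                       map_mmhg = 94, sbp_mmhg = 119)
  w <- sv_windows(sv, 60)
  expect_equal(w$sv_ml, c(100, 70, 90))
  # tie for the minimum resolved to the earliest sample
  sv2 <- tibble::tibble(time_s = c(0, 20, 40, 60), sv_ml = c(100, 70, 70, 90))
  expect_equal(sv_windows(sv2, 60)$time_s[2], 20)
  const <- tibble::tibble(time_s = c(0, 20, 40, 60), sv_ml = 90)
  expect_equal(unique(sv_windows(const, 60)$sv_ml), 90)
  nopre <- tibble::tibble(time_s = c(10, 30), sv_ml = c(1, 2))
  expect_error(sv_windows(nopre, 60), class = "dopplervti_error_input")
})

test_that("DSI is anti-monotone in VTI and SI anti-monotone in SBP", {
  vti <- seq(10, 30, 2)
  expect_true(all(diff(compute_dsi(72, vti)) < 0))
  sbp <- seq(90, 140, 5)
  expect_true(all(diff(compute_si(72, sbp)) < 0))
})
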