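test_that("beat waveform respects its amplitude bounds and endpoints", {
  w <- beat_waveform(beat_shape(100, 0, 0.15, 0), 0.5, 200)
  expect_equal(max(w$velocity_cm_s), 100) # grid hits the peak at phase 0.15
  expect_gte(min(w$velocity_cm_s), 0)
  expect_lt(min(w$velocity_cm_s), 1) # decays essentially to the EDV

  w20 <- beat_waveform(beat_shape(100, 20, 0.2, 0.1), 0.8, 200)
  expect_equal(w20$velocity_cm_s[1], 20) # starts at end-diastolic velocity
  expect_lte(max(w20$velocity_cm_s), 100 + 1e-9)
})

test_that("half-sine cycle integral matches the closed form and quadrature", {
  # closed form: 2 * Vp * T / pi for edv = 0
  sh <- beat_shape(100, 0, model = "halfsine")
  w <- beat_waveform(sh, 0.5, 2000)
  vti_trapz <- pracma::trapz(w$time_s, w$velocity_cm_s)
  closed_form <- 2 * 100 * 0.5 / pi
  oracle <- stats::integrate(function(t) 100 * sin(pi * t / 0.5), 0, 0.5)$value
  expect_equal(closed_form, oracle, tolerance = 1e-8)
  expect_equal(vti_trapz, closed_form, tolerance = 1e-3)
})

test_that("a nonzero notch depth produces exactly one dicrotic dip", {
  sh <- beat_shape(100, 10, 0.15, 0.25)
  w <- beat_waveform(sh, 0.8, 1000)
  v <- w$velocity_cm_s
  d <- diff(v)
  # count interior local minima: falling then rising
  minima <- sum(d[-length(d)] < 0 & d[-1] > 0)
  expect_equal(minima, 1)
  w0 <- beat_waveform(beat_shape(100, 10, 0.15, 0), 0.8, 1000)
  d0 <- diff(w0$velocity_cm_s)
  expect_equal(sum(d0[-length(d0)] < 0 & d0[-1] > 0), 0)
})

test_that("invalid shape parameters and too-coarse grids are rejected", {
  expect_error(beat_shape(100, 120), class = "dopplervti_error_parameter")
  expect_error(beat_shape(100, 20, 0.6), class = "dopplervti_error_parameter")
  expect_error(beat_shape(100, 20, 0.15, 1.2),
               class = "dopplervti_error_parameter")
  expect_error(beat_shape(-5, 0), class = "dopplervti_error_parameter")
  expect_error(beat_waveform(beat_shape(), 0.5, 10),
               class = "dopplervti_error_parameter")
})
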