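test_that("the calibrated responder preset encodes the programmed effect sizes", {
  p <- valsalva_preset("responder", jitter = FALSE)
  expect_equal(p$carotid_hold_vti_multiplier, 0.77)
  expect_equal(p$aortic_hold_vti_multiplier, 0.63)
  expect_equal(p$hold_sv_multiplier, 0.74)
  expect_equal(p$hold_map_multiplier, 1.04)
  # HR multiplier chosen so DSI change = 1.21/0.77 - 1 ~ +57% and
  # SI change = 1.21/hold_sbp_multiplier - 1 = +20%
  expect_equal(p$hold_hr_multiplier / p$carotid_hold_vti_multiplier - 1,
               0.571, tolerance = 0.01)
  expect_equal(p$hold_hr_multiplier / p$hold_sbp_multiplier - 1, 0.20,
               tolerance = 1e-9)
  expect_true(p$airway_pressure_cm_h2o >= 20 && p$airway_pressure_cm_h2o <= 25)
})

test_that("multiplier trajectories plateau at the programmed values in the windows", {
  phases <- c(15, 15, 15, 15)
  m <- dopplervti:::multiplier_at(seq(0, 60, 0.01), phases, 0.77, 1.02, 5)
  t <- seq(0, 60, 0.01)
  expect_true(all(m[t < 15] == 1))
  expect_true(all(abs(m[t >= 25 & t < 30] - 0.77) < 1e-12))
  expect_true(all(abs(m[t >= 55] - 1.02) < 1e-12))
  # monotone ramp within the hold
  ramp <- m[t >= 15 & t <= 25]
  expect_true(all(diff(ramp) <= 1e-12))
})

test_that("sham profiles stay inside the +/-8% aortic margin", {
  for (s in 1:20) {
    p <- valsalva_preset("sham", seed = s)
    expect_true(abs(p$aortic_hold_vti_multiplier - 1) <= 0.08 + 1e-9)
    expect_true(abs(p$carotid_hold_vti_multiplier - 1) <
                  abs(p$aortic_hold_vti_multiplier - 1) + 1e-9)
  }
})

test_that("profile validation rejects malformed inputs", {
  expect_error(valsalva_profile(phase_durations = c(15, 15, 15)),
               class = "dopplervti_error_config")
  expect_error(valsalva_profile(phase_durations = c(15, -1, 15, 15)),
               class = "dopplervti_error_config")
  expect_error(valsalva_profile(baseline_hr = 0),
               class = "dopplervti_error_config")
})
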