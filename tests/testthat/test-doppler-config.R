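test_that("Doppler equation arithmetic matches hand-derived values", {
  cfg <- doppler_config(carrier_frequency_hz = 4e6, speed_of_sound_m_s = 1540,
                        insonation_angle_deg = 0)
  # f = 2 f0 v cos(theta) / c: 2 * 4e6 * 1.0 / 1540
  expect_equal(velocity_to_frequency(100, cfg), 2 * 4e6 * 1.0 / 1540)
  expect_equal(frequency_to_velocity(5194.8, cfg), 100, tolerance = 1e-4)
  expect_equal(frequency_to_velocity(0, cfg), 0)
})

test_that("frequency/velocity conversion round-trips to machine precision", {
  cfg <- doppler_config(insonation_angle_deg = 37)
  f <- c(0, 12.5, 1000, 5195, 21000)
  expect_equal(velocity_to_frequency(frequency_to_velocity(f, cfg), cfg), f)
})

test_that("a 60-degree insonation angle doubles velocity for the same shift", {
  v0 <- frequency_to_velocity(3000, doppler_config(insonation_angle_deg = 0))
  v60 <- frequency_to_velocity(3000, doppler_config(insonation_angle_deg = 60))
  expect_equal(v60, 2 * v0)
})

test_that("degenerate geometry and invalid constants are rejected", {
  expect_error(doppler_config(insonation_angle_deg = 90),
               class = "dopplervti_error_config")
  expect_error(doppler_config(carrier_frequency_hz = 0),
               class = "dopplervti_error_config")
  expect_error(doppler_config(audio_sample_rate_hz = -1),
               class = "dopplervti_error_config")
})
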