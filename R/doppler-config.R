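#' Physical configuration of a Doppler ultrasound channel
#'
#' Bundles the constants that relate a Doppler audio frequency shift to a
#' blood velocity: the transducer carrier frequency, the speed of sound in
#' tissue, the insonation angle between beam and flow, and the audio sampling
#' rate of the recorded Doppler signal.
#'
#' The defaults (4 MHz carrier, 1540 m/s, 0 degrees, 44.1 kHz) place arterial
#' Doppler shifts comfortably inside the audio band: 100 cm/s of flow maps to
#' about 5.2 kHz. An insonation angle of 0 degrees corresponds to flow
#' directly along the beam, the convention used for suprasternal interrogation
#' of the descending aorta.
#'
#' @param carrier_frequency_hz Transducer carrier frequency f0 in Hz.
#' @param speed_of_sound_m_s Speed of sound c in tissue, m/s.
#' @param insonation_angle_deg Beam-to-flow angle theta in degrees; must be in
#'   `[0, 90)`.
#' @param audio_sample_rate_hz Sampling rate of the Doppler audio, Hz. Must
#'   exceed twice the largest Doppler shift to be represented.
#' @return An object of class `doppler_config` (a named list).
#' @examples
#' cfg <- doppler_config()
#' frequency_to_velocity(5194.8, cfg) # ~100 cm/s
#' @export
doppler_config <- function(carrier_frequency_hz = 4e6,
                           speed_of_sound_m_s = 1540,
                           insonation_angle_deg = 0,
                           audio_sample_rate_hz = 44100) {
  check_number(carrier_frequency_hz, "carrier_frequency_hz", lower = 0,
               allow_equal_lower = FALSE)
  check_number(speed_of_sound_m_s, "speed_of_sound_m_s", lower = 0,
               allow_equal_lower = FALSE)
  check_number(insonation_angle_deg, "insonation_angle_deg", lower = 0,
               upper = 90, allow_equal_upper = FALSE)
  check_number(audio_sample_rate_hz, "audio_sample_rate_hz", lower = 0,
               allow_equal_lower = FALSE)
  structure(
    list(
      carrier_frequency_hz = carrier_frequency_hz,
      speed_of_sound_m_s = speed_of_sound_m_s,
      insonation_angle_deg = insonation_angle_deg,
      audio_sample_rate_hz = audio_sample_rate_hz
    ),
    class = "doppler_config"
  )
}

#' @export
print.doppler_config <- function(x, ...) {
  cat("<doppler_config>\n")
  cat(sprintf("  carrier: %.3f MHz, c = %g m/s, angle = %g deg, audio rate = %g Hz\n",
              x$carrier_frequency_hz / 1e6, x$speed_of_sound_m_s,
              x$insonation_angle_deg, x$audio_sample_rate_hz))
  invisible(x)
}

#' Convert between Doppler frequency shift and blood velocity
#'
#' The Doppler equation for backscatter is `f = 2 * f0 * v * cos(theta) / c`.
#' `frequency_to_velocity()` inverts it, returning velocity in cm/s;
#' `velocity_to_frequency()` applies it, returning the shift in Hz. The two
#' are exact inverses.
#'
#' @param frequency_hz Doppler shift(s), Hz.
#' @param velocity_cm_s Blood velocity(ies), cm/s.
#' @param config A [doppler_config()].
#' @return Numeric vector: velocity in cm/s, or frequency in Hz.
#' @examples
#' cfg <- doppler_config(carrier_frequency_hz = 4e6)
#' velocity_to_frequency(100, cfg) # ~5194.8 Hz
#' @export
frequency_to_velocity <- function(frequency_hz, config = doppler_config()) {
  if (config$insonation_angle_deg >= 90) {
    abort_dv("Insonation angle >= 90 degrees leaves velocity undefined.", "config")
  }
  theta <- config$insonation_angle_deg * pi / 180
  v_m_s <- frequency_hz * config$speed_of_sound_m_s /
    (2 * config$carrier_frequency_hz * cos(theta))
  100 * v_m_s
}

#' @rdname frequency_to_velocity
#' @export
velocity_to_frequency <- function(velocity_cm_s, config = doppler_config()) {
  if (config$insonation_angle_deg >= 90) {
    abort_dv("Insonation angle >= 90 degrees leaves the shift undefined.", "config")
  }
  theta <- config$insonation_angle_deg * pi / 180
  2 * config$carrier_frequency_hz * (velocity_cm_s / 100) * cos(theta) /
    config$speed_of_sound_m_s
}
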