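# Shared fixtures, memoised so expensive simulations run once per session.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Calibrated responder ground truth (no jitter), shared across tests.
responder_track <- function() {
  memo("responder_track", {
    make_velocity_track(valsalva_preset("responder", jitter = FALSE), seed = 1)
  })
}

# Carotid channel of the responder track at SNR 20 dB, traced.
responder_traced <- function() {
  memo("responder_traced", {
    truth <- responder_track()
    audio <- synthesize_audio(truth, snr_db = 20, seed = 3)
    list(truth = truth,
         env = trace_envelope(audio, channel = "carotid"))
  })
}

# Slowly modulated envelope (variation within one 10 ms STFT window is well
# below one frequency bin), for tracer-accuracy checks.
slow_envelope <- function(duration = 20) {
  t <- seq(0, duration, by = 1 / 200)
  tibble::tibble(time_s = t, velocity_cm_s = 60 + 30 * sin(2 * pi * 0.25 * t))
}

# Ideal periodic envelope without any simulator involvement.
periodic_envelope <- function(hr_bpm = 60, duration = 10, frame_rate = 200,
                              peak = 100, edv = 20) {
  t <- seq(0, duration - 1 / frame_rate, by = 1 / frame_rate)
  rr <- 60 / hr_bpm
  shape <- beat_shape(peak, edv, 0.15, 0)
  phase <- (t %% rr) / rr
  tibble::tibble(time_s = t,
                 velocity_cm_s = dopplervti:::beat_velocity_at(shape, phase),
                 quality = TRUE)
}

one_bin_cm_s <- function() {
  frequency_to_velocity(100, doppler_config()) # 100 Hz bins at defaults
}
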