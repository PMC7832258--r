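#' Generate the ground-truth velocity tracks for one subject
#'
#' Builds beat-by-beat maximum-velocity envelopes for the carotid (CW patch)
#' and aortic (PW reference) channels over the full protocol. Beats share one
#' set of onsets (one heart): each beat's duration comes from the heart-rate
#' trajectory evaluated at its onset, and each channel's waveform is the
#' channel [beat_shape()] scaled so that the beat's true VTI equals
#' `vti_multiplier(onset) x baseline VTI` (amplitude is scaled by
#' `vti_mult x hr_mult` because compressing a beat in time shrinks its area).
#'
#' @param profile A [valsalva_profile()].
#' @param frame_rate Envelope sampling rate, Hz (default 200).
#' @param seed Integer seed for the beat-to-beat jitter draws.
#' @return An object of class `doppler_truth`: a list with
#'   `envelope` (named list of `velocity_envelope` tibbles: `carotid`,
#'   `aortic`), `beats` (named list of tibbles `onset_s`, `rr_s`, `hr_bpm`,
#'   `vti_cm`, `peak_cm_s`), `sv` (the [simulate_sv_channel()] tibble),
#'   `profile`, `frame_rate`, `seed`. Per-beat `vti_cm` equals the trapezoidal
#'   integral of the envelope over the beat by construction.
#' @examples
#' tr <- make_velocity_track(valsalva_preset("identity"), seed = 1)
#' range(diff(tr$beats$carotid$onset_s)) # constant RR
#' @export
make_velocity_track <- function(profile, frame_rate = 200, seed = 1) {
  stopifnot(inherits(profile, "valsalva_profile"))
  total <- sum(profile$phase_durations)
  max_hr <- profile$baseline_hr *
    max(1, profile$hold_hr_multiplier, profile$recovery_hr_multiplier)
  if (frame_rate < 8 * max_hr / 60) {
    abort_dv("`frame_rate` too low to resolve individual beats.", "config")
  }

  with_local_seed(seed, {
    plateau <- profile$window_length_s
    phases <- profile$phase_durations
    # --- shared beat onsets from the HR trajectory ---
    onsets <- c()
    rrs <- c()
    t <- 0
    while (t < total) {
      hr_mult <- multiplier_at(t, phases, profile$hold_hr_multiplier,
                               profile$recovery_hr_multiplier, plateau)
      jit <- if (profile$rr_jitter_sd > 0) {
        stats::rlnorm(1, 0, profile$rr_jitter_sd)
      } else 1
      rr <- 60 / (profile$baseline_hr * hr_mult) * jit
      onsets <- c(onsets, t)
      rrs <- c(rrs, rr)
      t <- t + rr
    }
    n_beats <- length(onsets)

    grid <- seq(0, total - 1 / frame_rate, by = 1 / frame_rate)
    beat_index <- findInterval(grid, onsets)
    phase_frac <- (grid - onsets[beat_index]) / rrs[beat_index]

    channels <- list(carotid = profile$carotid_shape,
                     aortic = profile$aortic_shape)
    hold_mult <- list(carotid = profile$carotid_hold_vti_multiplier,
                      aortic = profile$aortic_hold_vti_multiplier)
    rec_mult <- list(carotid = profile$carotid_recovery_vti_multiplier,
                     aortic = profile$aortic_recovery_vti_multiplier)

    envelopes <- list()
    beat_tables <- list()
    for (ch in names(channels)) {
      shape <- channels[[ch]]
      vti_mult <- multiplier_at(onsets, phases, hold_mult[[ch]],
                                rec_mult[[ch]], plateau)
      vjit <- if (profile$vti_jitter_sd > 0) {
        stats::rlnorm(n_beats, 0, profile$vti_jitter_sd)
      } else rep(1, n_beats)
      # amplitude scale per beat: vti_mult * (baseline RR / actual RR)
      amp <- vti_mult * vjit * (60 / profile$baseline_hr) / rrs

      v <- amp[beat_index] * beat_velocity_at(shape, phase_frac)
      env <- new_velocity_envelope(grid, v, quality = rep(TRUE, length(grid)))
      envelopes[[ch]] <- env

      # per-beat truth, restricted to beats fully inside the record
      complete <- which(onsets + rrs <= total + 1e-9)
      vti <- vapply(complete, function(i) {
        sel <- beat_index == i
        idx <- which(sel)
        # trapezoid across the beat, extended to the next onset sample
        idx2 <- c(idx, min(idx[length(idx)] + 1, length(grid)))
        pracma::trapz(grid[idx2], v[idx2])
      }, numeric(1))
      peak <- vapply(complete, function(i) max(v[beat_index == i]), numeric(1))
      beat_tables[[ch]] <- tibble::tibble(
        onset_s = onsets[complete],
        rr_s = rrs[complete],
        hr_bpm = 60 / rrs[complete],
        vti_cm = vti,
        peak_cm_s = peak
      )
    }

    sv <- simulate_sv_channel(profile, seed = NULL) # inherits local RNG

    structure(
      list(envelope = envelopes, beats = beat_tables, sv = sv,
           profile = profile, frame_rate = frame_rate, seed = seed),
      class = "doppler_truth"
    )
  })
}

#' Simulate the noninvasive stroke-volume monitor channel
#'
#' Emulates a pulse-contour monitor that reports stroke volume, MAP, and SBP
#' on a slow fixed cadence (default every 20 s), with the first sample taken
#' immediately before protocol onset (time 0). Values follow the profile's
#' slow-channel trajectory, which reaches the hold multiplier early in the
#' strain and holds it until shortly after release, so the during-protocol
#' minimum equals the programmed hold value.
#'
#' @param profile A [valsalva_profile()].
#' @param update_interval Monitor cadence, seconds (default 20).
#' @param seed Optional seed for multiplicative measurement noise; `NULL`
#'   uses the ambient RNG stream.
#' @param noise_sd Log-sd of multiplicative measurement noise applied to SV
#'   (0 disables; MAP/SBP are reported noise-free by the monitor model).
#' @return A tibble of class `sv_series`: `time_s`, `sv_ml`, `map_mmhg`,
#'   `sbp_mmhg`.
#' @export
simulate_sv_channel <- function(profile, update_interval = 20, seed = NULL,
                                noise_sd = 0) {
  stopifnot(inherits(profile, "valsalva_profile"))
  check_number(update_interval, "update_interval", lower = 0,
               allow_equal_lower = FALSE)
  total <- sum(profile$phase_durations)
  times <- seq(0, total, by = update_interval)
  phases <- profile$phase_durations
  pl <- profile$window_length_s
  run <- function() {
    sv <- profile$baseline_sv *
      slow_multiplier_at(times, phases, profile$hold_sv_multiplier,
                         profile$recovery_sv_multiplier, pl)
    if (noise_sd > 0) sv <- sv * stats::rlnorm(length(sv), 0, noise_sd)
    map <- profile$baseline_map *
      slow_multiplier_at(times, phases, profile$hold_map_multiplier,
                         profile$recovery_map_multiplier, pl)
    sbp <- profile$baseline_sbp *
      slow_multiplier_at(times, phases, profile$hold_sbp_multiplier,
                         profile$recovery_sbp_multiplier, pl)
    tibble::new_tibble(
      tibble::tibble(time_s = times, sv_ml = sv, map_mmhg = map,
                     sbp_mmhg = sbp),
      class = "sv_series"
    )
  }
  if (is.null(seed)) run() else with_local_seed(seed, run())
}

#' Synthesize two-channel Doppler audio from ground truth
#'
#' Converts the true maximum-velocity envelopes into audible Doppler signals
#' using the Doppler equation `f = 2 f0 v cos(theta) / c`. Each channel is a
#' sum of scatterer tones whose instantaneous frequencies are fixed fractions
#' of the envelope's shift. The fraction distribution emulates the blunt
#' (plug-like) velocity profile of large central arteries: by default 70% of
#' scatterers travel within 95--100% of the maximum velocity and the rest are
#' spread uniformly, so spectral power is concentrated just below the
#' envelope edge. White Gaussian noise is added at the requested SNR
#' (`snr_db = Inf` for noiseless audio); samples where the true velocity is
#' zero are gated to silence (emulating a wall filter). Output is normalised
#' to a peak amplitude of 0.9.
#'
#' @param truth A `doppler_truth` from [make_velocity_track()], or a plain
#'   envelope data frame (`time_s`, `velocity_cm_s`) to synthesize a single
#'   channel from an arbitrary known envelope.
#' @param config A [doppler_config()]; its audio sample rate must exceed
#'   twice the largest true Doppler shift.
#' @param snr_db Signal-to-noise ratio in dB (time-domain power ratio).
#' @param seed Integer seed; identical inputs and seed give bit-identical
#'   audio.
#' @param n_scatterers Number of scatterer tones per channel.
#' @param plug_fraction Fraction of scatterers in the fast "core" band.
#' @param plug_width Width of the core band as a fraction of the envelope.
#' @return An object of class `doppler_audio`: list with `samples` (matrix,
#'   one column per channel: carotid then aortic), `sample_rate_hz`,
#'   `channel_names`, `config`, `snr_db`, `seed`.
#' @export
synthesize_audio <- function(truth, config = doppler_config(), snr_db = 20,
                             seed = 1, n_scatterers = 96,
                             plug_fraction = 0.7, plug_width = 0.05) {
  if (is.data.frame(truth)) {
    check_envelope(truth)
    truth <- structure(
      list(envelope = list(signal = truth),
           frame_rate = 1 / stats::median(diff(truth$time_s))),
      class = "doppler_truth")
  }
  stopifnot(inherits(truth, "doppler_truth"))
  fs <- config$audio_sample_rate_hz
  max_v <- max(vapply(truth$envelope, function(e) max(e$velocity_cm_s),
                      numeric(1)))
  max_shift <- velocity_to_frequency(max_v, config)
  if (fs <= 2 * max_shift) {
    abort_dv(sprintf(
      "Audio sample rate %g Hz violates Nyquist for the largest shift %.0f Hz.",
      fs, max_shift), "config")
  }

  with_local_seed(seed, {
    cols <- lapply(truth$envelope, function(env) {
      # resample the envelope's shift onto the audio grid
      n <- round(max(env$time_s + 1 / truth$frame_rate) * fs)
      t_audio <- (seq_len(n) - 1) / fs
      f_shift <- stats::approx(env$time_s,
                               velocity_to_frequency(env$velocity_cm_s, config),
                               xout = t_audio, rule = 2)$y
      phase <- 2 * pi * cumsum(f_shift) / fs

      n_plug <- round(plug_fraction * n_scatterers)
      u <- c(stats::runif(n_plug, 1 - plug_width, 1),
             stats::runif(n_scatterers - n_plug, 0, 1))
      amp <- stats::runif(n_scatterers, 0.5, 1.5)
      phi0 <- stats::runif(n_scatterers, 0, 2 * pi)
      x <- numeric(n)
      block <- 262144L # bounded temporaries on long recordings
      for (b0 in seq(1L, n, by = block)) {
        b1 <- min(b0 + block - 1L, n)
        ph <- phase[b0:b1]
        acc <- numeric(b1 - b0 + 1L)
        for (k in seq_len(n_scatterers)) {
          acc <- acc + amp[k] * cos(u[k] * ph + phi0[k])
        }
        x[b0:b1] <- acc
      }
      x[f_shift <= 0] <- 0 # wall-filter gate: no flow, no audio
      p_sig <- mean(x^2)
      if (is.finite(snr_db) && p_sig > 0) {
        x <- x + stats::rnorm(n, 0, sqrt(p_sig / 10^(snr_db / 10)))
      }
      x
    })
    samples <- do.call(cbind, cols)
    peak <- max(abs(samples))
    if (peak > 0) samples <- samples * (0.9 / peak)
    structure(
      list(samples = samples, sample_rate_hz = fs,
           channel_names = names(truth$envelope), config = config,
           snr_db = snr_db, seed = seed),
      class = "doppler_audio"
    )
  })
}

#' Simulate one virtual subject (truth plus audio)
#'
#' @param profile A [valsalva_profile()].
#' @param config A [doppler_config()].
#' @param snr_db Audio SNR in dB.
#' @param seed Integer seed covering both track generation and audio noise.
#' @param frame_rate Envelope frame rate, Hz.
#' @return A list with elements `truth` (`doppler_truth`) and `audio`
#'   (`doppler_audio`).
#' @export
simulate_subject <- function(profile, config = doppler_config(), snr_db = 20,
                             seed = 1, frame_rate = 200) {
  truth <- make_velocity_track(profile, frame_rate = frame_rate, seed = seed)
  audio <- synthesize_audio(truth, config, snr_db = snr_db, seed = seed + 1)
  list(truth = truth, audio = audio)
}

#' Simulate a Valsalva cohort of responders and sham controls
#'
#' Responders use the `"responder"` preset with inter-subject multiplier
#' scatter; controls use the `"sham"` preset whose true aortic VTI change is
#' drawn within +/-8%, keeping a margin from the 10% decision boundary.
#' Per-subject seeds are derived deterministically from `seed`, so cohorts
#' are reproducible subject by subject. Audio is not generated here (it is
#' synthesized on demand by [analyze_cohort()] or [synthesize_audio()]), which
#' keeps large cohorts memory-light.
#'
#' @param n_responders,n_controls Subject counts; the total must be >= 1.
#' @param seed Master integer seed.
#' @param frame_rate Envelope frame rate, Hz.
#' @param jitter Disable to make every responder exactly the calibrated
#'   preset.
#' @return A tibble of class `valsalva_cohort` with columns `subject_id`,
#'   `group` (`"responder"`/`"control"`), `subject_seed`, and list-columns
#'   `profile` and `truth`.
#' @examples
#' co <- simulate_cohort(2, 2, seed = 42)
#' co$group
#' @export
simulate_cohort <- function(n_responders = 8, n_controls = 8, seed = 42,
                            frame_rate = 200, jitter = TRUE) {
  if (n_responders + n_controls < 1) {
    abort_dv("At least one subject is required.", "config")
  }
  groups <- c(rep("responder", n_responders), rep("control", n_controls))
  rows <- purrr::imap(groups, function(group, i) {
    sseed <- derive_subject_seed(seed, i)
    profile <- valsalva_preset(if (group == "responder") "responder" else "sham",
                               jitter = jitter, seed = sseed)
    truth <- make_velocity_track(profile, frame_rate = frame_rate,
                                 seed = sseed + 1)
    tibble::tibble(
      subject_id = sprintf("S%02d", i),
      group = group,
      subject_seed = sseed,
      profile = list(profile),
      truth = list(truth)
    )
  })
  tibble::new_tibble(dplyr::bind_rows(rows), class = "valsalva_cohort")
}
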