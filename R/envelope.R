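# Spectrogram front end and maximum-velocity envelope tracing.

new_velocity_envelope <- function(time_s, velocity_cm_s, quality = NULL) {
  if (is.null(quality)) quality <- rep(TRUE, length(time_s))
  tibble::new_tibble(
    tibble::tibble(time_s = time_s, velocity_cm_s = velocity_cm_s,
                   quality = quality),
    class = "velocity_envelope"
  )
}

#' Short-time Fourier power spectrogram of Doppler audio
#'
#' Frames the signal with a Hann window and returns one-sided linear power
#' per frame. The number of frames follows the standard framing rule
#' `floor((N - window_samples) / hop_samples) + 1`. Power is scaled as a
#' one-sided periodogram, `2 |X|^2 / (fs * sum(w^2))`, so that summing
#' `power * bin_width` over bins recovers the window-weighted signal power
#' (Parseval-consistent up to the one-sided folding of DC/Nyquist).
#'
#' @param audio Numeric vector of single-channel audio samples.
#' @param sample_rate Sampling rate, Hz.
#' @param window_length Analysis window length, seconds (default 10 ms).
#' @param hop Frame hop, seconds (default 2.5 ms).
#' @param nfft FFT length; defaults to the window length in samples (no zero
#'   padding), making the bin width exactly `1 / window_length`.
#' @return An object of class `doppler_spectrogram`: list with `frame_times`
#'   (window centres, s), `frequency_bins` (Hz), `power` (frames x bins
#'   matrix), `window_length`, `hop`, `sample_rate`.
#' @examples
#' sp <- compute_spectrogram(sin(2 * pi * 5000 * (0:44099) / 44100), 44100)
#' length(sp$frame_times) # 397
#' @export
compute_spectrogram <- function(audio, sample_rate, window_length = 0.010,
                                hop = 0.0025, nfft = NULL) {
  if (hop <= 0 || window_length < hop) {
    abort_dv("`window_length` >= `hop` > 0 is required.", "config")
  }
  win_n <- round(window_length * sample_rate)
  hop_n <- max(1L, round(hop * sample_rate))
  if (length(audio) < win_n) {
    abort_dv("Audio is shorter than one analysis window.", "input")
  }
  if (is.null(nfft)) nfft <- win_n
  if (nfft < win_n) {
    abort_dv("`nfft` must be at least the window length in samples.", "config")
  }

  n_frames <- floor((length(audio) - win_n) / hop_n) + 1
  starts <- (seq_len(n_frames) - 1L) * hop_n
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(win_n) - 1) / (win_n - 1)) # Hann
  n_bins <- nfft %/% 2 + 1
  scale <- 2 / (sample_rate * sum(w^2))

  # frame-block processing keeps peak allocation small on long recordings
  power <- matrix(0, n_frames, n_bins)
  block <- 2048L
  pad <- matrix(0, nfft - win_n, min(block, n_frames))
  for (b0 in seq(1L, n_frames, by = block)) {
    b1 <- min(b0 + block - 1L, n_frames)
    nb <- b1 - b0 + 1L
    idx <- outer(seq_len(win_n), starts[b0:b1], `+`)
    frames <- matrix(audio[idx], nrow = win_n) * w
    if (nfft > win_n) {
      frames <- rbind(frames, if (nb == ncol(pad)) pad else pad[, seq_len(nb),
                                                                drop = FALSE])
    }
    spec <- stats::mvfft(frames)
    power[b0:b1, ] <- t(Mod(spec[seq_len(n_bins), , drop = FALSE])^2) * scale
  }

  structure(
    list(
      frame_times = (starts + (win_n - 1) / 2) / sample_rate,
      frequency_bins = (seq_len(n_bins) - 1) * sample_rate / nfft,
      power = power,
      window_length = window_length,
      hop = hop_n / sample_rate,
      sample_rate = sample_rate
    ),
    class = "doppler_spectrogram"
  )
}

#' Trace the maximum Doppler frequency through a spectrogram
#'
#' Implements an integrated-power-percentile envelope estimator: for each
#' frame, the traced frequency is the lowest bin at which the cumulative
#' noise-corrected power (from 0 Hz upward) reaches `percentile` of the
#' frame's total noise-corrected power. The per-frame noise floor is the mean
#' power of the top `noise_floor_quantile` fraction of frequency bins (the
#' high-frequency tail, assumed signal-free). Frames whose total raw power
#' does not exceed `power_gate` times the extrapolated noise power are
#' declared signal-free: their traced frequency is 0 and their quality flag
#' is `FALSE`. The trace is median-filtered over `smooth_frames` frames.
#'
#' @param spec A `doppler_spectrogram`.
#' @param percentile Cumulative-power fraction defining the envelope,
#'   in (0, 1); default 0.95.
#' @param noise_floor_quantile Fraction of top frequency bins used for the
#'   noise floor estimate; default 0.1.
#' @param smooth_frames Odd median-filter length in frames; default 9 (22.5 ms
#'   at the default hop), enough to suppress single-frame speckle excursions.
#' @param power_gate Signal-presence gate relative to the noise floor.
#' @return A tibble: `time_s`, `frequency_hz`, `quality`.
#' @export
trace_max_frequency <- function(spec, percentile = 0.95,
                                noise_floor_quantile = 0.1,
                                smooth_frames = 9, power_gate = 2) {
  stopifnot(inherits(spec, "doppler_spectrogram"))
  if (percentile <= 0 || percentile >= 1) {
    abort_dv("`percentile` must lie strictly between 0 and 1.", "config")
  }
  if (smooth_frames %% 2 != 1) {
    abort_dv("`smooth_frames` must be odd.", "config")
  }
  P <- spec$power
  n_bins <- ncol(P)
  n_tail <- max(1L, floor(noise_floor_quantile * n_bins))
  tail_cols <- seq.int(n_bins - n_tail + 1L, n_bins)
  floor_per_frame <- rowMeans(P[, tail_cols, drop = FALSE])

  Pc <- P - floor_per_frame
  Pc[Pc < 0] <- 0
  total <- rowSums(Pc)
  raw_total <- rowSums(P)
  signal_present <- total > 0 &
    raw_total > power_gate * floor_per_frame * n_bins

  # cumulative power along bins; first bin reaching `percentile` of total
  cum <- Pc
  for (j in 2:ncol(cum)) cum[, j] <- cum[, j] + cum[, j - 1L]
  reached <- cum >= percentile * total # total recycles down rows (col-major)
  idx <- max.col(reached, ties.method = "first")
  idx[!signal_present] <- 1L
  freq <- spec$frequency_bins[idx]
  freq[!signal_present] <- 0

  if (length(freq) > smooth_frames) {
    freq <- as.numeric(stats::runmed(freq, smooth_frames, endrule = "keep"))
    freq[!signal_present] <- 0
  }
  tibble::tibble(time_s = spec$frame_times, frequency_hz = freq,
                 quality = signal_present)
}

#' Trace a velocity envelope from Doppler audio
#'
#' Convenience wrapper: [compute_spectrogram()] then [trace_max_frequency()]
#' then [frequency_to_velocity()].
#'
#' @param audio Numeric vector of single-channel audio, or a `doppler_audio`
#'   object together with `channel`.
#' @param sample_rate Sampling rate, Hz (taken from a `doppler_audio` input).
#' @param config A [doppler_config()] for the frequency-to-velocity
#'   conversion.
#' @param channel Channel name or index when `audio` is a `doppler_audio`.
#' @param ... Passed to [compute_spectrogram()] and [trace_max_frequency()]
#'   (`window_length`, `hop`, `nfft`, `percentile`, `noise_floor_quantile`,
#'   `smooth_frames`, `power_gate`).
#' @return A `velocity_envelope` tibble: `time_s`, `velocity_cm_s`,
#'   `quality`.
#' @export
trace_envelope <- function(audio, sample_rate = NULL,
                           config = doppler_config(), channel = 1, ...) {
  if (inherits(audio, "doppler_audio")) {
    if (is.character(channel)) {
      channel <- match(channel, audio$channel_names)
    }
    sample_rate <- audio$sample_rate_hz
    config <- audio$config
    audio <- audio$samples[, channel]
  }
  if (is.null(sample_rate)) {
    abort_dv("`sample_rate` is required for plain numeric audio.", "input")
  }
  dots <- list(...)
  spec_args <- dots[names(dots) %in% c("window_length", "hop", "nfft")]
  trace_args <- dots[names(dots) %in%
                       c("percentile", "noise_floor_quantile",
                         "smooth_frames", "power_gate")]
  spec <- do.call(compute_spectrogram,
                  c(list(audio = audio, sample_rate = sample_rate), spec_args))
  tr <- do.call(trace_max_frequency, c(list(spec = spec), trace_args))
  new_velocity_envelope(tr$time_s,
                        frequency_to_velocity(tr$frequency_hz, config),
                        tr$quality)
}
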