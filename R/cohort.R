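# End-to-end cohort analysis: audio -> envelope -> beats -> windows -> stats.

#' Analyze one subject from ground truth, bypassing the envelope tracer
#'
#' Segments the subject's true envelopes directly (no audio synthesis or
#' spectrogram), then applies the protocol windows. Used for calibration
#' checks where tracer error must be excluded.
#'
#' @param truth A `doppler_truth` from [make_velocity_track()].
#' @param windows A [define_windows()] tibble; defaults to the truth
#'   profile's phases.
#' @param ... Passed to [beat_table()].
#' @return A [subject_windows()] tibble.
#' @export
analyze_truth <- function(truth, windows = NULL, ...) {
  stopifnot(inherits(truth, "doppler_truth"))
  if (is.null(windows)) {
    windows <- define_windows(truth$profile$phase_durations,
                              truth$profile$window_length_s)
  }
  car <- beat_table(truth$envelope$carotid, ...)
  ao <- beat_table(truth$envelope$aortic, ...)
  subject_windows(car, ao, truth$sv, windows)
}

#' Analyze one subject through the full audio pipeline
#'
#' Synthesizes (or accepts) two-channel Doppler audio, traces the
#' maximum-velocity envelope of each channel, segments beats, and applies
#' the protocol windows.
#'
#' @param truth A `doppler_truth`.
#' @param audio A `doppler_audio`; synthesized from `truth` when `NULL`.
#' @param config A [doppler_config()] used when synthesizing.
#' @param snr_db Audio SNR when synthesizing.
#' @param seed Audio-noise seed when synthesizing.
#' @param windows A [define_windows()] tibble; defaults to the profile's
#'   phases.
#' @param trace_args,beat_args Named lists of extra arguments for
#'   [trace_envelope()] and [beat_table()].
#' @return A list: `windows` ([subject_windows()]), `changes`
#'   ([subject_changes()]), `envelopes` (named list of traced
#'   `velocity_envelope`s).
#' @export
analyze_subject <- function(truth, audio = NULL, config = doppler_config(),
                            snr_db = 20, seed = 1, windows = NULL,
                            trace_args = list(), beat_args = list()) {
  stopifnot(inherits(truth, "doppler_truth"))
  if (is.null(audio)) {
    audio <- synthesize_audio(truth, config, snr_db = snr_db, seed = seed)
  }
  if (is.null(windows)) {
    windows <- define_windows(truth$profile$phase_durations,
                              truth$profile$window_length_s)
  }
  envs <- lapply(seq_along(audio$channel_names), function(i) {
    do.call(trace_envelope, c(list(audio = audio, channel = i), trace_args))
  })
  names(envs) <- audio$channel_names
  beats <- lapply(envs, function(e) do.call(beat_table, c(list(env = e), beat_args)))
  w <- subject_windows(beats$carotid, beats$aortic, truth$sv, windows)
  list(windows = w, changes = subject_changes(w), envelopes = envs)
}

#' Analyze a simulated cohort end to end
#'
#' For each subject of a [simulate_cohort()] tibble: synthesize audio, trace
#' both envelopes, segment beats, window, and compute percent changes. Audio
#' is generated and discarded per subject. Ground-truth percent changes
#' (from the true beat tables) are carried alongside the measured ones so
#' that detection analyses can be labeled by truth.
#'
#' @param cohort A `valsalva_cohort` tibble from [simulate_cohort()].
#' @param config A [doppler_config()].
#' @param snr_db Audio SNR in dB.
#' @param use_truth_envelopes If `TRUE`, bypass audio synthesis and tracing
#'   and segment the true envelopes instead (calibration mode).
#' @param trace_args,beat_args Passed through to [analyze_subject()].
#' @param progress Print one line per subject.
#' @return A tibble of class `cohort_result`: one row per subject with
#'   `subject_id`, `group`, measured changes (`carotid_vti_pct`,
#'   `aortic_vti_pct`, `hr_pct`, `dsi_pct`, `si_pct`, `sv_pct`, `map_pct`,
#'   all T1 to T2), their T2 to T3 counterparts (`*_rec_pct`), and the
#'   ground-truth `true_aortic_vti_pct` and `true_carotid_vti_pct`. The
#'   per-subject window tables are kept in the `windows` list-column.
#' @export
analyze_cohort <- function(cohort, config = doppler_config(), snr_db = 20,
                           use_truth_envelopes = FALSE, trace_args = list(),
                           beat_args = list(), progress = FALSE) {
  stopifnot(is.data.frame(cohort), all(c("truth", "subject_id") %in% names(cohort)))
  rows <- purrr::pmap_dfr(
    cohort[, c("subject_id", "group", "subject_seed", "truth")],
    function(subject_id, group, subject_seed, truth) {
      if (progress) message("analyzing ", subject_id)
      windows <- define_windows(truth$profile$phase_durations,
                                truth$profile$window_length_s)
      w <- if (use_truth_envelopes) {
        analyze_truth(truth, windows)
      } else {
        analyze_subject(truth, config = config, snr_db = snr_db,
                        seed = subject_seed + 2, windows = windows,
                        trace_args = trace_args, beat_args = beat_args)$windows
      }
      cohort_result_row(subject_id, group, truth, w, windows)
    })
  tibble::new_tibble(rows, class = "cohort_result")
}

# One row of a cohort_result: measured changes from `w` plus ground-truth
# window changes from the subject's true beat tables.
cohort_result_row <- function(subject_id, group, truth, w, windows) {
  ch <- subject_changes(w)
  true_change <- function(beats) {
    sw <- subject_windows(dplyr::mutate(beats, kept = TRUE),
                          windows = windows)
    percent_change(sw$carotid_vti_cm[sw$window == "T1"],
                   sw$carotid_vti_cm[sw$window == "T2"])
  }
  g <- function(m, col) ch[[col]][ch$metric == m]
  tibble::tibble(
    subject_id = subject_id,
    group = group,
    carotid_vti_pct = g("carotid_vti", "t1_t2_pct"),
    aortic_vti_pct = g("aortic_vti", "t1_t2_pct"),
    hr_pct = g("hr", "t1_t2_pct"),
    dsi_pct = g("dsi", "t1_t2_pct"),
    si_pct = g("si", "t1_t2_pct"),
    sv_pct = g("sv", "t1_t2_pct"),
    map_pct = g("map", "t1_t2_pct"),
    carotid_vti_rec_pct = g("carotid_vti", "t2_t3_pct"),
    aortic_vti_rec_pct = g("aortic_vti", "t2_t3_pct"),
    dsi_rec_pct = g("dsi", "t2_t3_pct"),
    true_carotid_vti_pct = true_change(truth$beats$carotid),
    true_aortic_vti_pct = true_change(truth$beats$aortic),
    programmed_aortic_vti_pct =
      100 * (truth$profile$aortic_hold_vti_multiplier - 1),
    windows = list(w)
  )
}

#' Cohort statistics: paired t-tests and threshold detection
#'
#' Reproduces the statistical layer of the protocol analysis on a
#' [analyze_cohort()] result: paired two-tailed t-tests comparing T1 vs T2
#' window values per metric, and sensitivity/specificity of detecting a
#' >= `threshold` percent true fall in aortic VTI using the carotid VTI
#' (fall direction), the DSI (rise), and the shock index (rise) as
#' predictors, each evaluated at the fixed threshold and across the full
#' threshold sweep.
#'
#' @param result A `cohort_result` tibble.
#' @param threshold Reference-change criterion and default decision
#'   threshold, percent (default 10).
#' @param truth_from Source of the reference labels. `"programmed"`
#'   (default) uses the effect size each subject's profile was built with
#'   (responders are programmed well past a 10% aortic fall, sham controls
#'   within +/-8% of no change, so classes are separated by construction);
#'   `"realized"` uses the ground-truth beat tables, whose window means
#'   additionally carry beat-to-beat jitter; `"measured"` uses the traced
#'   aortic change, as one would with real recordings.
#' @return A list of class `cohort_stats`: `t_tests` (tibble: metric, t, df,
#'   p), `detection` (tibble: one row per predictor with fixed-threshold and
#'   best-threshold metrics), `sweeps` (named list of [sweep_thresholds()]
#'   tibbles), `threshold`, `n`.
#' @export
cohort_stats <- function(result, threshold = 10,
                         truth_from = c("programmed", "realized", "measured")) {
  truth_from <- match.arg(truth_from)
  stopifnot(inherits(result, "cohort_result") || is.data.frame(result))

  # paired t-tests on window values (T1 vs T2), per metric
  pull_window <- function(col, win) {
    vapply(result$windows, function(w) w[[col]][w$window == win], numeric(1))
  }
  t_tests <- purrr::map_dfr(
    c(carotid_vti_cm = "carotid_vti_cm", aortic_vti_cm = "aortic_vti_cm",
      hr_bpm = "hr_bpm", dsi = "dsi"),
    function(col) {
      x <- pull_window(col, "T1")
      y <- pull_window(col, "T2")
      if (any(is.na(x)) || any(is.na(y))) {
        return(tibble::tibble(metric = col, estimate = NA_real_,
                              statistic = NA_real_, df = NA_real_,
                              p_value = NA_real_, n = sum(!is.na(x))))
      }
      dplyr::bind_cols(tibble::tibble(metric = col), paired_t_test(x, y))
    })

  ref_change <- switch(truth_from,
                       programmed = result$programmed_aortic_vti_pct,
                       realized = result$true_aortic_vti_pct,
                       measured = result$aortic_vti_pct)
  truth <- ref_change <= -threshold

  predictors <- list(
    carotid_vti = list(values = result$carotid_vti_pct, direction = "fall"),
    dsi = list(values = result$dsi_pct, direction = "rise"),
    si = list(values = result$si_pct, direction = "rise")
  )
  predictors <- purrr::keep(predictors, ~ !all(is.na(.x$values)))

  sweeps <- list()
  detection <- purrr::imap_dfr(predictors, function(p, name) {
    fixed <- detection_metrics(truth, p$values, threshold, p$direction)
    sw <- sweep_thresholds(truth, p$values, p$direction)
    sweeps[[name]] <<- sw
    best <- attr(sw, "best_threshold")
    best_row <- sw[which.max(sw$youden), ]
    tibble::tibble(
      predictor = name,
      direction = p$direction,
      sensitivity = fixed$sensitivity,
      specificity = fixed$specificity,
      separation_margin = fixed$separation_margin,
      best_threshold = best,
      best_sensitivity = best_row$sensitivity,
      best_specificity = best_row$specificity,
      perfect_separation = attr(sw, "perfect_separation")
    )
  })

  structure(
    list(t_tests = t_tests, detection = detection, sweeps = sweeps,
         threshold = threshold, n = nrow(result)),
    class = "cohort_stats"
  )
}

#' @export
print.cohort_stats <- function(x, ...) {
  cat(sprintf("<cohort_stats> n = %d subjects, reference criterion: %g%% aortic VTI fall\n",
              x$n, x$threshold))
  cat("Paired t-tests (T1 vs T2):\n")
  print(as.data.frame(x$t_tests), digits = 4)
  cat("Detection of the reference fall:\n")
  print(as.data.frame(x$detection), digits = 4)
  invisible(x)
}
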