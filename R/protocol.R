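# Protocol windowing (T1/T2/T3), Doppler Shock Index, percent changes.

#' Define the T1/T2/T3 analysis windows from phase durations
#'
#' T1 (baseline) is the 5-s window starting 5 s into the resting baseline;
#' T2 (peak strain) is the terminal 5 s of the inspiratory hold; T3
#' (recovery) is the terminal 5 s of the final recovery phase. All windows
#' are half-open `[start, end)`. For the default 15/15/15/15-s protocol this
#' yields T1 = [5, 10), T2 = [25, 30), T3 = [55, 60).
#'
#' @param phase_durations Four positive phase durations (s); each must be at
#'   least `window_length`.
#' @param window_length Window length, seconds (default 5).
#' @return A tibble of class `protocol_windows`: `window`, `start_s`,
#'   `end_s`.
#' @examples
#' define_windows(c(15, 15, 15, 15))
#' @export
define_windows <- function(phase_durations, window_length = 5) {
  if (length(phase_durations) != 4L || any(!is.finite(phase_durations))) {
    abort_dv("`phase_durations` must be four finite durations.", "config")
  }
  if (any(phase_durations < window_length)) {
    abort_dv(sprintf(
      "Every protocol phase must last at least %g s (got %s).",
      window_length, paste(phase_durations, collapse = ", ")), "config")
  }
  p <- phase_durations
  total <- sum(p)
  t1_start <- min(window_length, p[1] - window_length)
  tibble::new_tibble(
    tibble::tibble(
      window = c("T1", "T2", "T3"),
      start_s = c(t1_start, p[1] + p[2] - window_length, total - window_length),
      end_s = c(t1_start + window_length, p[1] + p[2], total)
    ),
    class = "protocol_windows"
  )
}

#' Mean VTI and heart rate of beats inside a window
#'
#' Averages kept beats whose onset falls inside the half-open interval
#' `[start, end)` (unweighted mean).
#'
#' @param beats A [beat_table()] (or any tibble with `onset_s`, `vti_cm`,
#'   `hr_bpm`, optional `kept`).
#' @param start,end Window bounds, seconds.
#' @return A one-row tibble: `n_beats`, `vti_cm`, `hr_bpm`, `peak_cm_s`.
#'   Errors with class `dopplervti_error_missing_window` if the window holds
#'   no kept beats.
#' @export
window_mean <- function(beats, start, end) {
  kept <- if ("kept" %in% names(beats)) beats$kept else TRUE
  sel <- kept & beats$onset_s >= start & beats$onset_s < end
  if (!any(sel)) {
    abort_dv(sprintf("No kept beats with onset inside [%g, %g).", start, end),
             "missing_window")
  }
  tibble::tibble(
    n_beats = sum(sel),
    vti_cm = mean(beats$vti_cm[sel]),
    hr_bpm = mean(beats$hr_bpm[sel]),
    peak_cm_s = if ("peak_cm_s" %in% names(beats)) {
      mean(beats$peak_cm_s[sel])
    } else NA_real_
  )
}

#' Doppler Shock Index and shock index
#'
#' The Doppler Shock Index (DSI) replaces the systolic blood pressure in the
#' denominator of the classic shock index with the common carotid VTI:
#' `DSI = HR / VTI` (bpm/cm). The shock index is `SI = HR / SBP`
#' (bpm/mm Hg).
#'
#' @param hr Heart rate, bpm.
#' @param vti Carotid VTI, cm; must be positive.
#' @param sbp Systolic blood pressure, mm Hg; must be positive.
#' @return Numeric vector.
#' @examples
#' compute_dsi(72, 18) # 4
#' compute_si(72, 119) # ~0.605
#' @export
compute_dsi <- function(hr, vti) {
  if (any(!is.finite(vti)) || any(vti <= 0)) {
    abort_dv("VTI must be positive to form the DSI.", "domain")
  }
  hr / vti
}

#' @rdname compute_dsi
#' @export
compute_si <- function(hr, sbp) {
  if (any(!is.finite(sbp)) || any(sbp <= 0)) {
    abort_dv("SBP must be positive to form the shock index.", "domain")
  }
  hr / sbp
}

#' Percent change between two values
#'
#' `100 * (b - a) / a`: the conventional "changed by x%" between a reference
#' value `a` and a later value `b`.
#'
#' @param a Reference value(s); must be nonzero.
#' @param b Comparison value(s).
#' @return Percent change(s).
#' @examples
#' percent_change(20, 15.4) # -23
#' @export
percent_change <- function(a, b) {
  if (any(!is.finite(a)) || any(a == 0)) {
    abort_dv("Reference value `a` must be finite and nonzero.", "domain")
  }
  100 * (b - a) / a
}

#' Window values of the slow stroke-volume monitor channel
#'
#' Applies the monitor windowing convention: T1 is the sample immediately
#' before protocol onset (the latest sample with `time_s <= 0`); T2 is the
#' sample with the smallest SV inside `(0, protocol_duration]` (ties broken
#' by earliest time); T3 is the last sample at or before
#' `protocol_duration`. MAP and SBP are read from the same rows.
#'
#' @param sv An `sv_series` tibble (`time_s`, `sv_ml`, `map_mmhg`,
#'   optionally `sbp_mmhg`).
#' @param protocol_duration Protocol length, seconds (default 60).
#' @return A tibble: `window`, `time_s`, `sv_ml`, `map_mmhg`, `sbp_mmhg`.
#' @examples
#' sv <- tibble::tibble(time_s = c(0, 20, 40, 60),
#'                      sv_ml = c(100, 80, 70, 90),
#'                      map_mmhg = 94, sbp_mmhg = 119)
#' sv_windows(sv, 60)$sv_ml # 100 70 90
#' @export
sv_windows <- function(sv, protocol_duration = 60) {
  if (!all(c("time_s", "sv_ml") %in% names(sv))) {
    abort_dv("`sv` must have columns `time_s` and `sv_ml`.", "input")
  }
  pre <- which(sv$time_s <= 0)
  if (length(pre) == 0) {
    abort_dv("No monitor sample at or before protocol onset (time 0).",
             "input")
  }
  i1 <- pre[length(pre)]
  during <- which(sv$time_s > 0 & sv$time_s <= protocol_duration)
  if (length(during) == 0) {
    abort_dv("No monitor samples during the protocol.", "input")
  }
  i2 <- during[which.min(sv$sv_ml[during])] # which.min takes the earliest tie
  at_end <- which(sv$time_s <= protocol_duration)
  i3 <- at_end[length(at_end)]
  rows <- c(i1, i2, i3)
  tibble::tibble(
    window = c("T1", "T2", "T3"),
    time_s = sv$time_s[rows],
    sv_ml = sv$sv_ml[rows],
    map_mmhg = if ("map_mmhg" %in% names(sv)) sv$map_mmhg[rows] else NA_real_,
    sbp_mmhg = if ("sbp_mmhg" %in% names(sv)) sv$sbp_mmhg[rows] else NA_real_
  )
}

#' Per-window hemodynamics for one subject
#'
#' Combines carotid and aortic beat tables with the slow monitor channel into
#' the per-window summary: mean carotid/aortic VTI, mean heart rate, DSI,
#' shock index, SV, and MAP for T1, T2, T3. Window-level DSI and SI are
#' formed from window-mean HR and window-mean VTI/SBP (set
#' `per_beat_dsi = TRUE` to average per-beat DSI values instead).
#'
#' @param carotid_beats,aortic_beats [beat_table()]s for the two channels
#'   (`aortic_beats` may be `NULL` if only the patch channel is available).
#' @param sv An `sv_series` tibble or `NULL`.
#' @param windows A [define_windows()] tibble.
#' @param per_beat_dsi Average per-beat DSI instead of ratio-of-means.
#' @return A tibble of class `subject_windows` with one row per window:
#'   `window`, `n_beats`, `carotid_vti_cm`, `aortic_vti_cm`, `hr_bpm`,
#'   `dsi`, `si`, `sv_ml`, `map_mmhg`, `sbp_mmhg`.
#' @export
subject_windows <- function(carotid_beats, aortic_beats = NULL, sv = NULL,
                            windows = define_windows(c(15, 15, 15, 15)),
                            per_beat_dsi = FALSE) {
  rows <- purrr::pmap_dfr(windows, function(window, start_s, end_s) {
    car <- window_mean(carotid_beats, start_s, end_s)
    ao <- if (!is.null(aortic_beats)) {
      window_mean(aortic_beats, start_s, end_s)
    } else tibble::tibble(vti_cm = NA_real_)
    dsi <- if (per_beat_dsi) {
      sel <- carotid_beats$kept & carotid_beats$onset_s >= start_s &
        carotid_beats$onset_s < end_s
      mean(compute_dsi(carotid_beats$hr_bpm[sel], carotid_beats$vti_cm[sel]))
    } else {
      compute_dsi(car$hr_bpm, car$vti_cm)
    }
    tibble::tibble(
      window = window,
      n_beats = car$n_beats,
      carotid_vti_cm = car$vti_cm,
      aortic_vti_cm = ao$vti_cm,
      hr_bpm = car$hr_bpm,
      dsi = dsi
    )
  })
  if (!is.null(sv)) {
    svw <- sv_windows(sv, protocol_duration = max(windows$end_s))
    rows <- dplyr::left_join(rows, svw[, c("window", "sv_ml", "map_mmhg",
                                           "sbp_mmhg")], by = "window")
    rows$si <- compute_si(rows$hr_bpm, rows$sbp_mmhg)
  } else {
    rows$sv_ml <- NA_real_
    rows$map_mmhg <- NA_real_
    rows$sbp_mmhg <- NA_real_
    rows$si <- NA_real_
  }
  tibble::new_tibble(rows, class = "subject_windows")
}

#' Percent changes across protocol windows for one subject
#'
#' @param windows_tbl A [subject_windows()] tibble.
#' @return A tibble of class `subject_changes`: one row per metric
#'   (`carotid_vti`, `aortic_vti`, `hr`, `dsi`, `si`, `sv`, `map`) with
#'   `t1_t2_pct` and `t2_t3_pct`.
#' @export
subject_changes <- function(windows_tbl) {
  stopifnot(all(c("T1", "T2", "T3") %in% windows_tbl$window))
  w <- function(win) windows_tbl[windows_tbl$window == win, ]
  metrics <- c(carotid_vti = "carotid_vti_cm", aortic_vti = "aortic_vti_cm",
               hr = "hr_bpm", dsi = "dsi", si = "si", sv = "sv_ml",
               map = "map_mmhg")
  purrr::imap_dfr(metrics, function(col, name) {
    a <- w("T1")[[col]]; b <- w("T2")[[col]]; c3 <- w("T3")[[col]]
    tibble::tibble(
      metric = name,
      t1_t2_pct = if (is.na(a) || is.na(b)) NA_real_ else percent_change(a, b),
      t2_t3_pct = if (is.na(b) || is.na(c3)) NA_real_ else percent_change(b, c3)
    )
  }) |> tibble::new_tibble(class = "subject_changes")
}
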