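# Cardiac-cycle segmentation and per-beat VTI / heart rate.

#' Detect cardiac-cycle onsets in a velocity envelope
#'
#' Finds systolic peaks (local maxima separated by at least the refractory
#' period, with prominence at least `min_prominence_fraction` of the median
#' peak prominence) and places each beat onset at the foot of the systolic
#' upstroke: the tangent at the maximum of the envelope's positive derivative
#' preceding the peak, projected back to the level of the preceding trough
#' (the intersecting-tangent convention; for a sharp-footed upstroke this is
#' the derivative maximum itself).
#'
#' @param env A `velocity_envelope` tibble (`time_s`, `velocity_cm_s`,
#'   optional `quality`), e.g. from [trace_envelope()]. Must cover at least
#'   2 s.
#' @param refractory Minimum separation between successive peaks, seconds
#'   (default 0.3 s, capping detectable heart rate at 200 bpm).
#' @param min_prominence_fraction Peaks whose prominence falls below this
#'   fraction of the median peak prominence are ignored.
#' @return Numeric vector of onset times (s), strictly increasing.
#' @export
detect_beats <- function(env, refractory = 0.3,
                         min_prominence_fraction = 0.3) {
  check_envelope(env)
  check_number(refractory, "refractory", lower = 0, allow_equal_lower = FALSE)
  t <- env$time_s
  v <- env$velocity_cm_s
  if (diff(range(t)) < 2) {
    abort_dv("Envelope must cover at least 2 seconds.", "insufficient_signal")
  }
  dt <- stats::median(diff(t))
  vs <- if (length(v) > 9) as.numeric(stats::runmed(v, 9)) else v
  refr_n <- max(1L, round(refractory / dt))

  if (max(vs) - min(vs) <= 0) {
    abort_dv("Envelope is flat; no beats detectable.", "insufficient_signal")
  }
  peaks <- find_local_peaks(vs, refr_n,
                            min_height = min(vs) + 0.25 * (max(vs) - min(vs)))
  if (length(peaks) < 2) {
    abort_dv("Fewer than two systolic peaks found.", "insufficient_signal")
  }

  # prominence: drop to the lowest point between neighbouring peaks
  bounds <- c(1L, peaks, length(vs))
  prom <- vapply(seq_along(peaks), function(i) {
    left <- min(vs[bounds[i]:peaks[i]])
    right <- min(vs[peaks[i]:bounds[i + 2L]])
    vs[peaks[i]] - max(left, right)
  }, numeric(1))
  keep <- prom >= min_prominence_fraction * stats::median(prom)
  peaks <- peaks[keep]
  if (length(peaks) < 2) {
    abort_dv("Fewer than two beats survive the prominence filter.",
             "insufficient_signal")
  }

  dv <- diff(vs)
  onsets <- vapply(seq_along(peaks), function(i) {
    lo <- if (i == 1) 1L else peaks[i - 1]
    win <- lo:(max(peaks[i] - 1L, lo))
    j <- win[which.max(dv[win])] # steepest point of the upstroke
    # intersecting-tangent foot: project the max-slope tangent back to the
    # level of the preceding trough (equals j itself for a sharp-footed rise)
    trough <- min(vs[lo:j])
    foot <- t[j] - (vs[j] - trough) * dt / max(dv[j], .Machine$double.eps)
    max(foot, t[lo])
  }, numeric(1))
  onsets <- onsets[c(TRUE, diff(onsets) > 0)]
  if (length(onsets) < 2) {
    abort_dv("Fewer than two distinct beat onsets found.", "insufficient_signal")
  }
  onsets
}

#' Per-beat velocity time integral
#'
#' Integrates the envelope trapezoidally over each beat interval
#' `[onset_i, onset_{i+1})` on the native frame grid; velocities in cm/s
#' times seconds give a VTI in cm. The final partial beat (after the last
#' onset) is discarded. Beats containing frames flagged as signal-free are
#' marked `kept = FALSE` and recorded in the `"dropped"` attribute.
#'
#' @param env A `velocity_envelope`.
#' @param onsets Strictly increasing onset times from [detect_beats()]
#'   (at least 2).
#' @return A tibble with one row per complete beat: `onset_s`, `duration_s`,
#'   `vti_cm`, `peak_cm_s`, `kept`.
#' @examples
#' env <- tibble::tibble(time_s = seq(0, 2, 0.005),
#'                       velocity_cm_s = 50, quality = TRUE)
#' compute_beat_vti(env, c(0, 1, 2))$vti_cm # 50 50
#' @export
compute_beat_vti <- function(env, onsets) {
  check_envelope(env)
  if (length(onsets) < 2 || any(diff(onsets) <= 0)) {
    abort_dv("At least two strictly increasing onsets are required.", "input")
  }
  t <- env$time_s
  v <- env$velocity_cm_s
  q <- if ("quality" %in% names(env)) env$quality else rep(TRUE, length(t))
  n_beats <- length(onsets) - 1L
  res <- purrr::map_dfr(seq_len(n_beats), function(i) {
    sel <- t >= onsets[i] & t < onsets[i + 1]
    idx <- which(sel)
    if (length(idx) < 2) {
      return(tibble::tibble(onset_s = onsets[i],
                            duration_s = onsets[i + 1] - onsets[i],
                            vti_cm = NA_real_, peak_cm_s = NA_real_,
                            kept = FALSE))
    }
    # extend to the first frame of the next beat so the trapezoid covers
    # the full half-open interval
    idx2 <- c(idx, min(idx[length(idx)] + 1L, length(t)))
    tibble::tibble(
      onset_s = onsets[i],
      duration_s = onsets[i + 1] - onsets[i],
      vti_cm = pracma::trapz(t[idx2], v[idx2]),
      peak_cm_s = max(v[idx]),
      kept = all(q[idx])
    )
  })
  attr(res, "dropped") <- res$onset_s[!res$kept]
  res
}

#' Instantaneous heart rate from beat onsets
#'
#' `hr[i] = 60 / (onset[i+1] - onset[i])`, one value per complete beat.
#'
#' @param onsets Strictly increasing onset times (s), at least 2.
#' @return Numeric vector of per-beat heart rates, bpm (length
#'   `length(onsets) - 1`).
#' @examples
#' compute_hr(c(0, 1, 2)) # 60 60
#' @export
compute_hr <- function(onsets) {
  if (length(onsets) < 2) {
    abort_dv("At least two onsets are required.", "input")
  }
  if (any(diff(onsets) <= 0)) {
    abort_dv("Onset times must be strictly increasing.", "input")
  }
  60 / diff(onsets)
}

#' Segment an envelope into a beat table
#'
#' Runs [detect_beats()], [compute_beat_vti()], and [compute_hr()] and
#' assembles the canonical per-beat table used by the protocol layer.
#'
#' @inheritParams detect_beats
#' @param ... Passed to [detect_beats()] (`refractory`,
#'   `min_prominence_fraction`).
#' @return A tibble of class `beat_table`: `onset_s`, `rr_s`, `hr_bpm`,
#'   `vti_cm`, `peak_cm_s`, `kept`.
#' @export
beat_table <- function(env, ...) {
  onsets <- detect_beats(env, ...)
  vti <- compute_beat_vti(env, onsets)
  tibble::new_tibble(
    tibble::tibble(
      onset_s = vti$onset_s,
      rr_s = vti$duration_s,
      hr_bpm = compute_hr(onsets),
      vti_cm = vti$vti_cm,
      peak_cm_s = vti$peak_cm_s,
      kept = vti$kept
    ),
    class = "beat_table"
  )
}

# Local maxima above `min_height`, at least `min_dist` samples apart.
# Plateau maxima (flat tops from median smoothing) count once, at their
# first sample; when two candidates fall inside the refractory distance the
# higher one wins (greedy, tallest first).
find_local_peaks <- function(v, min_dist, min_height = -Inf) {
  n <- length(v)
  if (n < 3) return(integer(0))
  d <- diff(v)
  rising <- c(FALSE, d > 0)
  falling_next <- logical(n)
  # next nonzero slope after i is downward
  nz <- which(d != 0)
  next_slope <- rep(NA_real_, n)
  if (length(nz) > 0) {
    next_slope[seq_len(n - 1)] <- stats::approx(
      nz, d[nz], xout = seq_len(n - 1), method = "constant", f = 1,
      rule = 2)$y
  }
  cand <- which(rising & !is.na(next_slope) & next_slope < 0 &
                  v >= min_height)
  if (length(cand) == 0) return(integer(0))
  keep <- logical(length(cand))
  taken <- rep(FALSE, n)
  for (j in order(v[cand], decreasing = TRUE)) {
    i <- cand[j]
    lo <- max(1L, i - min_dist)
    hi <- min(n, i + min_dist)
    if (!any(taken[lo:hi])) {
      keep[j] <- TRUE
      taken[i] <- TRUE
    }
  }
  sort(cand[keep])
}

check_envelope <- function(env) {
  if (!is.data.frame(env) ||
      !all(c("time_s", "velocity_cm_s") %in% names(env))) {
    abort_dv("Envelope must be a data frame with `time_s` and `velocity_cm_s`.",
             "input")
  }
  if (nrow(env) > 1 && any(diff(env$time_s) <= 0)) {
    abort_dv("Envelope `time_s` must be strictly increasing.", "input")
  }
  invisible(env)
}
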