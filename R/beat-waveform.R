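#' Arterial beat waveform shape parameters
#'
#' Describes the maximum-velocity waveform of a single cardiac cycle. Two
#' models are available:
#'
#' * `"pulse"` (default): a fast systolic upstroke (quarter-sine rise to the
#'   peak at `systolic_rise_fraction` of the cycle), followed by an
#'   exponential diastolic decay that lands exactly back on the end-diastolic
#'   velocity, with an optional dicrotic notch (a Gaussian dip after the
#'   peak).
#' * `"halfsine"`: the symmetric degenerate mode `v(x) = edv + (psv - edv) *
#'   sin(pi * x)`, whose cycle integral has the closed form
#'   `edv * T + 2 * (psv - edv) * T / pi`. Used as an analytic oracle.
#'
#' @param peak_systolic_velocity Peak systolic velocity (PSV), cm/s.
#' @param end_diastolic_velocity End-diastolic velocity (EDV), cm/s; the curve
#'   starts and ends here. `0 <= edv < psv`.
#' @param systolic_rise_fraction Fraction of the cycle from onset to the
#'   systolic peak, in `(0, 0.5)`. Ignored by the `"halfsine"` model.
#' @param dicrotic_notch_depth Depth of the dicrotic notch as a fraction of
#'   PSV, in `[0, 1)`. `0` disables the notch.
#' @param model `"pulse"` or `"halfsine"`.
#' @return An object of class `beat_shape`.
#' @examples
#' sh <- beat_shape(100, 0, model = "halfsine")
#' w <- beat_waveform(sh, beat_duration = 0.5, frame_rate = 1000)
#' max(w$velocity_cm_s) # 100
#' @export
beat_shape <- function(peak_systolic_velocity = 100,
                       end_diastolic_velocity = 20,
                       systolic_rise_fraction = 0.15,
                       dicrotic_notch_depth = 0.15,
                       model = c("pulse", "halfsine")) {
  model <- match.arg(model)
  check_number(peak_systolic_velocity, "peak_systolic_velocity", lower = 0,
               allow_equal_lower = FALSE, class = "parameter")
  check_number(end_diastolic_velocity, "end_diastolic_velocity", lower = 0,
               upper = peak_systolic_velocity, allow_equal_upper = FALSE,
               class = "parameter")
  check_number(systolic_rise_fraction, "systolic_rise_fraction", lower = 0,
               upper = 0.5, allow_equal_lower = FALSE,
               allow_equal_upper = FALSE, class = "parameter")
  check_number(dicrotic_notch_depth, "dicrotic_notch_depth", lower = 0,
               upper = 1, allow_equal_upper = FALSE, class = "parameter")
  structure(
    list(
      peak_systolic_velocity = peak_systolic_velocity,
      end_diastolic_velocity = end_diastolic_velocity,
      systolic_rise_fraction = systolic_rise_fraction,
      dicrotic_notch_depth = dicrotic_notch_depth,
      model = model
    ),
    class = "beat_shape"
  )
}

# Velocity at cycle phase x in [0, 1); vectorised over x. The pulse model is
# built so that v(0) = v(1) = edv and max v = psv exactly at x = rise.
beat_velocity_at <- function(shape, x) {
  psv <- shape$peak_systolic_velocity
  edv <- shape$end_diastolic_velocity
  r <- shape$systolic_rise_fraction
  x <- x %% 1

  if (shape$model == "halfsine") {
    return(edv + (psv - edv) * sin(pi * x))
  }

  v <- numeric(length(x))
  rising <- x <= r
  v[rising] <- edv + (psv - edv) * sin(pi * x[rising] / (2 * r))

  # Diastolic limb: exponential decay with a linear correction pinning
  # v(1) = edv exactly.
  k <- 4 / (1 - r) # decay rate: ~4 time constants across diastole
  xd <- x[!rising]
  d <- exp(-k * (xd - r))
  d_end <- exp(-k * (1 - r))
  v[!rising] <- edv + (psv - edv) * (d - d_end * (xd - r) / (1 - r))

  if (shape$dicrotic_notch_depth > 0) {
    xn <- r + 0.3 * (1 - r)   # notch centre, early diastole
    wn <- 0.05 * (1 - r)      # notch width
    notch <- shape$dicrotic_notch_depth * psv * exp(-((x - xn) / wn)^2 / 2)
    notch[rising] <- 0
    v <- pmax(v - notch, 0)
    # restore exact endpoint (notch tail is negligible there but be strict)
    v[x == 0] <- edv
  }
  v
}

#' Sample one cardiac cycle of a beat waveform
#'
#' Evaluates the velocity curve of a single beat on a uniform time grid.
#'
#' @param shape A [beat_shape()].
#' @param beat_duration Cycle length, seconds.
#' @param frame_rate Sampling rate of the returned curve, Hz. At least 8
#'   samples per beat are required.
#' @return A tibble with columns `time_s` and `velocity_cm_s`; the first
#'   sample lies at time 0 and the grid stops just short of `beat_duration`
#'   (the next cycle's first sample).
#' @examples
#' w <- beat_waveform(beat_shape(100, 20), 0.8, 200)
#' w$velocity_cm_s[1] # 20, end-diastolic velocity
#' @export
beat_waveform <- function(shape, beat_duration, frame_rate) {
  check_number(beat_duration, "beat_duration", lower = 0,
               allow_equal_lower = FALSE, class = "parameter")
  check_number(frame_rate, "frame_rate", lower = 0, allow_equal_lower = FALSE,
               class = "parameter")
  n <- floor(beat_duration * frame_rate)
  if (n < 8) {
    abort_dv("frame_rate x beat_duration must give at least 8 samples per beat.",
             "parameter")
  }
  t <- seq(0, by = 1 / frame_rate, length.out = n)
  tibble::tibble(time_s = t,
                 velocity_cm_s = beat_velocity_at(shape, t / beat_duration))
}

# Cycle-average of the shape (fraction of psv-scaled area), i.e. the integral
# of beat_velocity_at over one unit phase. Used to convert between beat VTI
# and amplitude. Computed by fine-grid quadrature once per shape.
beat_shape_area <- function(shape, n = 4096) {
  x <- seq(0, 1, length.out = n + 1)
  v <- beat_velocity_at(shape, pmin(x, 1 - 1e-12))
  pracma::trapz(x, v)
}
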