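#' Programmable hemodynamic profile of a virtual Valsalva subject
#'
#' A `valsalva_profile` defines the ground-truth hemodynamic trajectory of one
#' simulated subject over the four-phase protocol: resting baseline,
#' inspiratory hold (strain against 20--25 cm H2O), release hold, and
#' recovery. Each tracked quantity (per-beat VTI on the carotid and aortic
#' channels, heart rate, stroke volume, MAP, SBP) follows a smooth multiplier
#' trajectory: 1 during baseline, a monotone ramp across the hold reaching the
#' `hold_*_multiplier` over the terminal plateau of the hold, then a ramp to
#' the `recovery_*_multiplier` holding over the terminal plateau of recovery.
#' The plateaus coincide with the analysis windows (see [define_windows()]),
#' so window means equal the programmed multipliers exactly when jitter is
#' disabled.
#'
#' @param phase_durations Four positive phase durations in seconds
#'   (baseline, inspiratory hold, release hold, recovery); default 15 s each.
#' @param baseline_hr Resting heart rate, bpm.
#' @param hold_hr_multiplier,recovery_hr_multiplier Heart-rate scale at the
#'   end of the hold and end of recovery.
#' @param carotid_shape,aortic_shape [beat_shape()] for each Doppler channel.
#' @param carotid_hold_vti_multiplier,carotid_recovery_vti_multiplier True
#'   per-beat carotid VTI scale at end-of-hold and end-of-recovery.
#' @param aortic_hold_vti_multiplier,aortic_recovery_vti_multiplier Same for
#'   the aortic reference channel.
#' @param baseline_sv,hold_sv_multiplier,recovery_sv_multiplier Stroke volume
#'   (mL) channel of the noninvasive monitor.
#' @param baseline_map,hold_map_multiplier,recovery_map_multiplier Mean
#'   arterial pressure (mm Hg) channel.
#' @param baseline_sbp,hold_sbp_multiplier,recovery_sbp_multiplier Systolic
#'   blood pressure (mm Hg) used by the shock index.
#' @param airway_pressure_cm_h2o Target strain pressure (annotation only).
#' @param rr_jitter_sd Log-sd of multiplicative beat-to-beat RR jitter.
#' @param vti_jitter_sd Log-sd of multiplicative per-beat VTI jitter
#'   (independent per channel).
#' @param window_length_s Length of the terminal plateaus, matching the 5-s
#'   analysis windows.
#' @return An object of class `valsalva_profile`.
#' @seealso [valsalva_preset()] for calibrated presets.
#' @export
valsalva_profile <- function(phase_durations = c(15, 15, 15, 15),
                             baseline_hr = 72,
                             hold_hr_multiplier = 1,
                             recovery_hr_multiplier = 1,
                             carotid_shape = beat_shape(100, 20, 0.15, 0.15),
                             aortic_shape = beat_shape(100, 5, 0.12, 0.10),
                             carotid_hold_vti_multiplier = 1,
                             carotid_recovery_vti_multiplier = 1,
                             aortic_hold_vti_multiplier = 1,
                             aortic_recovery_vti_multiplier = 1,
                             baseline_sv = 106,
                             hold_sv_multiplier = 1,
                             recovery_sv_multiplier = 1,
                             baseline_map = 94,
                             hold_map_multiplier = 1,
                             recovery_map_multiplier = 1,
                             baseline_sbp = 119,
                             hold_sbp_multiplier = 1,
                             recovery_sbp_multiplier = 1,
                             airway_pressure_cm_h2o = 22.5,
                             rr_jitter_sd = 0.02,
                             vti_jitter_sd = 0.03,
                             window_length_s = 5) {
  if (length(phase_durations) != 4L || !all(is.finite(phase_durations)) ||
      any(phase_durations <= 0)) {
    abort_dv("`phase_durations` must be four positive durations in seconds.",
             "config")
  }
  for (nm in c("baseline_hr", "hold_hr_multiplier", "recovery_hr_multiplier",
               "carotid_hold_vti_multiplier", "carotid_recovery_vti_multiplier",
               "aortic_hold_vti_multiplier", "aortic_recovery_vti_multiplier",
               "baseline_sv", "hold_sv_multiplier", "recovery_sv_multiplier",
               "baseline_map", "hold_map_multiplier", "recovery_map_multiplier",
               "baseline_sbp", "hold_sbp_multiplier", "recovery_sbp_multiplier")) {
    check_number(get(nm), nm, lower = 0, allow_equal_lower = FALSE)
  }
  check_number(rr_jitter_sd, "rr_jitter_sd", lower = 0)
  check_number(vti_jitter_sd, "vti_jitter_sd", lower = 0)
  check_number(window_length_s, "window_length_s", lower = 0,
               allow_equal_lower = FALSE)
  stopifnot(inherits(carotid_shape, "beat_shape"),
            inherits(aortic_shape, "beat_shape"))
  structure(
    list(
      phase_durations = as.numeric(phase_durations),
      baseline_hr = baseline_hr,
      hold_hr_multiplier = hold_hr_multiplier,
      recovery_hr_multiplier = recovery_hr_multiplier,
      carotid_shape = carotid_shape,
      aortic_shape = aortic_shape,
      carotid_hold_vti_multiplier = carotid_hold_vti_multiplier,
      carotid_recovery_vti_multiplier = carotid_recovery_vti_multiplier,
      aortic_hold_vti_multiplier = aortic_hold_vti_multiplier,
      aortic_recovery_vti_multiplier = aortic_recovery_vti_multiplier,
      baseline_sv = baseline_sv,
      hold_sv_multiplier = hold_sv_multiplier,
      recovery_sv_multiplier = recovery_sv_multiplier,
      baseline_map = baseline_map,
      hold_map_multiplier = hold_map_multiplier,
      recovery_map_multiplier = recovery_map_multiplier,
      baseline_sbp = baseline_sbp,
      hold_sbp_multiplier = hold_sbp_multiplier,
      recovery_sbp_multiplier = recovery_sbp_multiplier,
      airway_pressure_cm_h2o = airway_pressure_cm_h2o,
      rr_jitter_sd = rr_jitter_sd,
      vti_jitter_sd = vti_jitter_sd,
      window_length_s = window_length_s
    ),
    class = "valsalva_profile"
  )
}

#' @export
print.valsalva_profile <- function(x, ...) {
  cat("<valsalva_profile>\n")
  cat(sprintf("  phases: %s s (total %g s), HR %g bpm x%.3g (hold)\n",
              paste(x$phase_durations, collapse = "/"),
              sum(x$phase_durations), x$baseline_hr, x$hold_hr_multiplier))
  cat(sprintf("  VTI hold multipliers: carotid %.3g, aortic %.3g\n",
              x$carotid_hold_vti_multiplier, x$aortic_hold_vti_multiplier))
  cat(sprintf("  SV %g mL x%.3g, MAP %g x%.3g, SBP %g x%.3g\n",
              x$baseline_sv, x$hold_sv_multiplier, x$baseline_map,
              x$hold_map_multiplier, x$baseline_sbp, x$hold_sbp_multiplier))
  invisible(x)
}

# Multiplier trajectory shared by HR and both VTI channels:
#   baseline -> ramp across the hold -> hold plateau (last `plateau` s of the
#   hold) -> ramp across release+recovery -> recovery plateau (last
#   `plateau` s of the protocol).
multiplier_at <- function(t, phases, hold_mult, recovery_mult, plateau = 5) {
  p1 <- phases[1]; p2 <- phases[2]
  total <- sum(phases)
  hold_end <- p1 + p2
  ramp1 <- smoothstep((t - p1) / max(p2 - plateau, 1e-9))
  m <- 1 + (hold_mult - 1) * ramp1
  ramp2 <- smoothstep((t - hold_end) / max(total - hold_end - plateau, 1e-9))
  after <- t >= hold_end
  m[after] <- hold_mult + (recovery_mult - hold_mult) * ramp2[after]
  m
}

# Slow-channel (SV/MAP/SBP monitor) trajectory: reaches the hold multiplier
# within `plateau` s of strain onset and holds it until `plateau` s after
# release, then ramps to the recovery multiplier by protocol end. This makes
# the 20-s monitor samples land on the programmed plateau values.
slow_multiplier_at <- function(t, phases, hold_mult, recovery_mult, plateau = 5) {
  p1 <- phases[1]; p2 <- phases[2]
  total <- sum(phases)
  plateau_start <- p1 + plateau
  plateau_end <- p1 + p2 + plateau
  m <- 1 + (hold_mult - 1) * smoothstep((t - p1) / plateau)
  after <- t >= plateau_end
  ramp2 <- smoothstep((t - plateau_end) / max(total - plateau_end, 1e-9))
  m[after] <- hold_mult + (recovery_mult - hold_mult) * ramp2[after]
  m
}

#' Calibrated Valsalva profile presets
#'
#' Three presets cover the simulation scenarios used throughout the package:
#'
#' * `"responder"`: a subject whose strain produces the group-mean effect
#'   sizes of a healthy-volunteer Valsalva cohort: carotid VTI -23% and
#'   aortic VTI -37% from baseline to the end of the hold, stroke volume
#'   -26%, MAP +4%, heart rate +21% (so the Doppler Shock Index rises
#'   1.21/0.77 - 1 = +57% and the shock index 1.21/1.00833 - 1 = +20%),
#'   with recovery overshoot reproducing the +115% (aortic) and +32%
#'   (carotid) hold-to-recovery rebounds.
#' * `"sham"`: a control subject who does not strain effectively; the true
#'   aortic VTI change is drawn uniformly in +/-8% (inside the 10% decision
#'   margin), the carotid change scaled proportionally, HR essentially flat.
#' * `"identity"`: all multipliers 1 and all jitter 0; every beat is
#'   identical. Used for oracle tests.
#'
#' @param name Preset name.
#' @param jitter If `FALSE`, beat-to-beat and inter-subject jitter are
#'   disabled (deterministic trajectories).
#' @param seed Seed used by the `"sham"` preset to draw its true effect and,
#'   when `jitter = TRUE`, by `"responder"` to draw inter-subject multiplier
#'   scatter (multiplicative log-normal, sd 0.05).
#' @return A [valsalva_profile()].
#' @examples
#' p <- valsalva_preset("responder", jitter = FALSE)
#' p$carotid_hold_vti_multiplier # 0.77
#' @export
valsalva_preset <- function(name = c("responder", "sham", "identity"),
                            jitter = TRUE, seed = NULL) {
  name <- match.arg(name)
  if (name == "identity") {
    return(valsalva_profile(rr_jitter_sd = 0, vti_jitter_sd = 0))
  }
  if (name == "responder") {
    j <- function(m) m # multiplier scatter, identity when jitter is off
    if (jitter) {
      scatter <- with_local_seed(seed, stats::rlnorm(6, 0, 0.05))
      j <- local({
        i <- 0
        function(m) {
          i <<- i + 1
          m * scatter[i]
        }
      })
    }
    hold_car <- j(0.77)
    hold_ao <- j(0.63)
    hold_hr <- j(1.21)
    rec_car <- hold_car * j(1.32)
    rec_ao <- hold_ao * j(2.15)
    hold_sv <- j(0.74)
    return(valsalva_profile(
      baseline_hr = 72,
      hold_hr_multiplier = hold_hr,
      recovery_hr_multiplier = 1,
      carotid_hold_vti_multiplier = hold_car,
      carotid_recovery_vti_multiplier = rec_car,
      aortic_hold_vti_multiplier = hold_ao,
      aortic_recovery_vti_multiplier = rec_ao,
      baseline_sv = 106, hold_sv_multiplier = hold_sv,
      recovery_sv_multiplier = 1,
      baseline_map = 94, hold_map_multiplier = 1.04,
      baseline_sbp = 119, hold_sbp_multiplier = 1.21 / 1.20,
      rr_jitter_sd = if (jitter) 0.02 else 0,
      vti_jitter_sd = if (jitter) 0.03 else 0
    ))
  }
  # sham: true aortic change uniform in [-8, +8] %, carotid scaled by the
  # responder carotid/aortic effect ratio (23/37), HR near flat.
  draws <- with_local_seed(seed, stats::runif(2))
  ao_change <- -0.08 + 0.16 * draws[1]
  car_change <- ao_change * (23 / 37)
  hr_mult <- if (jitter) exp(stats::qnorm(draws[2]) * 0.02) else 1
  valsalva_profile(
    baseline_hr = 72,
    hold_hr_multiplier = hr_mult,
    recovery_hr_multiplier = 1,
    carotid_hold_vti_multiplier = 1 + car_change,
    carotid_recovery_vti_multiplier = 1,
    aortic_hold_vti_multiplier = 1 + ao_change,
    aortic_recovery_vti_multiplier = 1,
    baseline_sv = 106, hold_sv_multiplier = 1 + ao_change * 0.7,
    baseline_map = 94, hold_map_multiplier = 1.01,
    baseline_sbp = 119, hold_sbp_multiplier = 1.005,
    rr_jitter_sd = if (jitter) 0.02 else 0,
    vti_jitter_sd = if (jitter) 0.03 else 0
  )
}
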