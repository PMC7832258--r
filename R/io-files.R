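# CSV/JSON artifact readers and writers with format validation.

#' Read and write velocity-envelope CSV files
#'
#' The envelope format has columns `time_s`, `velocity_cm_s`,
#' `quality_flag` (0/1). `read_envelope_csv()` validates the header and the
#' monotonicity of the time column, reporting the offending line on failure;
#' `write_envelope_csv()` writes the complement so that
#' `read(write(x))` reproduces `x` to float round-trip.
#'
#' @param env A `velocity_envelope` tibble.
#' @param path File path.
#' @return `read_envelope_csv()`: a `velocity_envelope` tibble;
#'   `write_envelope_csv()`: the path, invisibly.
#' @export
write_envelope_csv <- function(env, path) {
  check_envelope(env)
  out <- tibble::tibble(
    time_s = env$time_s,
    velocity_cm_s = env$velocity_cm_s,
    quality_flag = as.integer(if ("quality" %in% names(env)) {
      env$quality
    } else rep(1L, nrow(env)))
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_envelope_csv
#' @export
read_envelope_csv <- function(path) {
  df <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) abort_dv(paste0("Cannot parse envelope CSV: ",
                                        conditionMessage(e)), "format")
  )
  need <- c("time_s", "velocity_cm_s")
  missing <- setdiff(need, names(df))
  if (nrow(df) == 0) {
    abort_dv("Envelope CSV has no data rows.", "format")
  }
  if (length(missing) > 0) {
    abort_dv(paste0("Envelope CSV is missing column(s): ",
                    paste(missing, collapse = ", ")), "format")
  }
  bad <- which(diff(df$time_s) <= 0)
  if (length(bad) > 0) {
    abort_dv(sprintf(
      "Envelope time column is not strictly increasing at data line %d.",
      bad[1] + 1L), "format")
  }
  quality <- if ("quality_flag" %in% names(df)) {
    as.logical(df$quality_flag)
  } else rep(TRUE, nrow(df))
  new_velocity_envelope(df$time_s, df$velocity_cm_s, quality)
}

#' Write per-beat and monitor-channel CSV artifacts
#'
#' `write_beats_csv()` stores a [beat_table()] (columns `onset_s`, `rr_s`,
#' `hr_bpm`, `vti_cm`, `peak_cm_s`, `kept_flag`); `write_sv_csv()` stores an
#' `sv_series` (`time_s`, `sv_ml`, `map_mmhg`, `sbp_mmhg`).
#'
#' @param beats A [beat_table()].
#' @param sv An `sv_series` tibble.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_beats_csv <- function(beats, path) {
  out <- tibble::tibble(
    onset_s = beats$onset_s, rr_s = beats$rr_s, hr_bpm = beats$hr_bpm,
    vti_cm = beats$vti_cm, peak_cm_s = beats$peak_cm_s,
    kept_flag = as.integer(if ("kept" %in% names(beats)) beats$kept else 1L)
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_beats_csv
#' @export
write_sv_csv <- function(sv, path) {
  readr::write_csv(tibble::as_tibble(sv), path)
  invisible(path)
}
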