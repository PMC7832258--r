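# ggplot2 visualisations for the main result types.

#' Plot a velocity envelope
#'
#' Velocity against time, with signal-free (masked) frames marked along the
#' time axis.
#'
#' @param object A `velocity_envelope` tibble.
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.velocity_envelope <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s,
                                            y = .data$velocity_cm_s)) +
    ggplot2::geom_line(linewidth = 0.3, colour = "#2c5f8a") +
    ggplot2::labs(x = "time (s)", y = "maximum velocity (cm/s)")
  if ("quality" %in% names(object) && any(!object$quality)) {
    p <- p + ggplot2::geom_rug(
      data = object[!object$quality, ], sides = "b", colour = "red",
      alpha = 0.4)
  }
  p
}

#' Plot a beat table
#'
#' Per-beat VTI over the protocol, with dropped beats hollow.
#'
#' @param object A [beat_table()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.beat_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$onset_s, y = .data$vti_cm,
                                       shape = .data$kept)) +
    ggplot2::geom_point(colour = "#8a2c2c") +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                guide = "none") +
    ggplot2::labs(x = "beat onset (s)", y = "VTI (cm)")
}

#' Separation plot for a cohort result
#'
#' Dot plot of per-subject percent changes for each predictor, split by the
#' ground-truth label, with the decision threshold drawn. Perfectly
#' separated classes show no overlap across the threshold line.
#'
#' @param result A `cohort_result` from [analyze_cohort()].
#' @param threshold Reference criterion, percent.
#' @return A ggplot object.
#' @export
plot_separation <- function(result, threshold = 10) {
  long <- tidyr::pivot_longer(
    dplyr::select(result, "subject_id", "group", "true_aortic_vti_pct",
                  "carotid_vti_pct", "dsi_pct", "si_pct"),
    cols = c("carotid_vti_pct", "dsi_pct", "si_pct"),
    names_to = "predictor", values_to = "change_pct")
  long$truth <- ifelse(long$true_aortic_vti_pct <= -threshold,
                       sprintf(">=%g%% aortic fall", threshold),
                       sprintf("<%g%% aortic fall", threshold))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$truth, y = .data$change_pct,
                                     colour = .data$group)) +
    ggplot2::geom_jitter(width = 0.08, height = 0, size = 2, alpha = 0.8) +
    ggplot2::geom_hline(yintercept = c(-threshold, threshold),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::facet_wrap(~predictor, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "measured change T1 to T2 (%)")
}

#' Plot a threshold sweep
#'
#' Sensitivity and specificity as functions of the decision threshold.
#'
#' @param sweep A [sweep_thresholds()] tibble.
#' @return A ggplot object.
#' @export
plot_threshold_sweep <- function(sweep) {
  long <- tidyr::pivot_longer(sweep, c("sensitivity", "specificity"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$threshold, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "decision threshold (percentage points)", y = NULL)
}
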