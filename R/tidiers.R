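# broom-style tidy()/glance() methods.

#' Tidy a cohort statistics object
#'
#' Returns one row per fitted quantity: the paired t-tests (term =
#' `t_test_<metric>`) and the detection metrics per predictor (term =
#' `detection_<predictor>`).
#'
#' @param x A [cohort_stats()] object.
#' @param ... Ignored.
#' @return A tibble with columns `term`, `estimate`, `statistic`, `df`,
#'   `p_value`, `sensitivity`, `specificity`, `separation_margin`.
#' @exportS3Method generics::tidy
tidy.cohort_stats <- function(x, ...) {
  tt <- dplyr::transmute(
    x$t_tests,
    term = paste0("t_test_", .data$metric),
    estimate = .data$estimate,
    statistic = .data$statistic,
    df = .data$df,
    p_value = .data$p_value,
    sensitivity = NA_real_,
    specificity = NA_real_,
    separation_margin = NA_real_
  )
  dt <- dplyr::transmute(
    x$detection,
    term = paste0("detection_", .data$predictor),
    estimate = NA_real_,
    statistic = NA_real_,
    df = NA_real_,
    p_value = NA_real_,
    sensitivity = .data$sensitivity,
    specificity = .data$specificity,
    separation_margin = .data$separation_margin
  )
  dplyr::bind_rows(tt, dt)
}

#' @rdname tidy.cohort_stats
#' @exportS3Method generics::glance
glance.cohort_stats <- function(x, ...) {
  tibble::tibble(
    n_subjects = x$n,
    threshold_pct = x$threshold,
    all_predictors_perfect = all(x$detection$perfect_separation),
    min_sensitivity = min(x$detection$sensitivity, na.rm = TRUE),
    min_specificity = min(x$detection$specificity, na.rm = TRUE)
  )
}

#' Tidy a cohort result
#'
#' Pivots the per-subject percent changes into long form: one row per
#' subject and metric.
#'
#' @param x A `cohort_result` from [analyze_cohort()].
#' @param ... Ignored.
#' @return A tibble: `subject_id`, `group`, `metric`, `change_pct`.
#' @exportS3Method generics::tidy
tidy.cohort_result <- function(x, ...) {
  tidyr::pivot_longer(
    dplyr::select(x, -"windows"),
    cols = dplyr::ends_with("_pct"),
    names_to = "metric", values_to = "change_pct"
  ) |>
    dplyr::mutate(metric = sub("_pct$", "", .data$metric)) |>
    dplyr::select("subject_id", "group", "metric", "change_pct")
}

#' @rdname tidy.cohort_result
#' @exportS3Method generics::glance
glance.cohort_result <- function(x, ...) {
  tibble::tibble(
    n_subjects = nrow(x),
    n_responders = sum(x$group == "responder"),
    n_controls = sum(x$group == "control"),
    mean_carotid_vti_pct = mean(x$carotid_vti_pct),
    mean_aortic_vti_pct = mean(x$aortic_vti_pct),
    mean_dsi_pct = mean(x$dsi_pct)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
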