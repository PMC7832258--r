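# Paired t-tests and threshold detection metrics.

#' Paired two-tailed Student t-test
#'
#' Tests whether paired measurements changed between two conditions using
#' differences `d = y - x` (after minus before): `t = mean(d) / (sd(d) /
#' sqrt(n))` with the sample standard deviation (n - 1 denominator),
#' `df = n - 1`, and a two-tailed p-value from the t distribution.
#'
#' @param x Baseline values, one per subject.
#' @param y Follow-up values, same length.
#' @return A one-row tibble: `estimate` (mean difference), `statistic` (t),
#'   `df`, `p_value`, `n`. Errors with class
#'   `dopplervti_error_degenerate` when all differences are identical
#'   (zero variance).
#' @examples
#' paired_t_test(c(1, 2, 3), c(2, 3, 5)) # t = 4, df = 2, p ~ 0.057
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) {
    abort_dv("`x` and `y` must have equal length >= 2.", "input")
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    abort_dv("Inputs must be finite.", "input")
  }
  d <- y - x
  n <- length(d)
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    abort_dv("All paired differences are identical; the t statistic is undefined.",
             "degenerate")
  }
  t_stat <- mean(d) / (sd_d / sqrt(n))
  df <- n - 1
  tibble::tibble(
    estimate = mean(d),
    statistic = t_stat,
    df = df,
    p_value = 2 * stats::pt(-abs(t_stat), df),
    n = n
  )
}

#' Sensitivity and specificity of a percent-change threshold detector
#'
#' A subject is predicted positive when its percent change crosses the
#' decision threshold in the stated direction: for `direction = "fall"`,
#' `change <= -threshold`; for `direction = "rise"` (DSI, shock index),
#' `change >= +threshold`. Sensitivity is TP/(TP+FN) against the supplied
#' truth labels, specificity TN/(TN+FP). The separation margin is the
#' smallest predictor magnitude among true positives minus the largest
#' magnitude among true negatives (positive iff the classes are perfectly
#' separable by some magnitude threshold).
#'
#' @param truth Logical vector: did the reference variable truly cross its
#'   criterion (e.g. a >= 10% fall in aortic VTI)?
#' @param predictor Percent changes of the predictor variable, same length.
#' @param threshold Decision threshold in percentage points (default 10).
#' @param direction `"fall"` or `"rise"`.
#' @return A one-row tibble of class `detection_result`: `threshold`,
#'   `direction`, `tp`, `fn`, `tn`, `fp`, `sensitivity`, `specificity`,
#'   `separation_margin`. An empty truth class yields `NA` for its rate, not
#'   0.
#' @examples
#' detection_metrics(c(TRUE, TRUE, FALSE, FALSE), c(-15, -12, -3, 5), 10, "fall")
#' @export
detection_metrics <- function(truth, predictor, threshold = 10,
                              direction = c("fall", "rise")) {
  direction <- match.arg(direction)
  if (length(truth) != length(predictor)) {
    abort_dv("`truth` and `predictor` must have the same length.", "input")
  }
  truth <- as.logical(truth)
  predicted <- if (direction == "fall") {
    predictor <= -threshold
  } else {
    predictor >= threshold
  }
  tp <- sum(predicted & truth)
  fn <- sum(!predicted & truth)
  tn <- sum(!predicted & !truth)
  fp <- sum(predicted & !truth)
  margin <- if (any(truth) && any(!truth)) {
    min(abs(predictor[truth])) - max(abs(predictor[!truth]))
  } else {
    NA_real_
  }
  tibble::new_tibble(
    tibble::tibble(
      threshold = threshold,
      direction = direction,
      tp = tp, fn = fn, tn = tn, fp = fp,
      sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
      separation_margin = margin
    ),
    class = "detection_result"
  )
}

#' Sweep every distinguishable decision threshold
#'
#' Evaluates [detection_metrics()] at the midpoints between successive sorted
#' predictor values (mapped into the stated direction), plus one threshold
#' below and one above all observed values. Reports Youden's index
#' (`sensitivity + specificity - 1`) per threshold and whether any threshold
#' achieves perfect separation.
#'
#' @inheritParams detection_metrics
#' @return A tibble: `threshold`, `sensitivity`, `specificity`, `youden`,
#'   with attributes `perfect_separation` (logical) and `best_threshold`
#'   (lowest threshold maximizing Youden's index).
#' @export
sweep_thresholds <- function(truth, predictor, direction = c("fall", "rise")) {
  direction <- match.arg(direction)
  truth <- as.logical(truth)
  if (!any(truth) || all(truth)) {
    abort_dv("Both truth classes must be non-empty for a threshold sweep.",
             "input")
  }
  # score increases with "more positive": fall -> -change, rise -> +change
  score <- if (direction == "fall") -predictor else predictor
  s <- sort(unique(score))
  cand <- c(s[1] - 1, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2,
            s[length(s)] + 1)
  res <- purrr::map_dfr(cand, function(th) {
    m <- detection_metrics(truth, predictor, threshold = th,
                           direction = direction)
    tibble::tibble(threshold = th, sensitivity = m$sensitivity,
                   specificity = m$specificity,
                   youden = m$sensitivity + m$specificity - 1)
  })
  best <- res$threshold[which.max(res$youden)]
  attr(res, "perfect_separation") <- any(res$sensitivity == 1 &
                                           res$specificity == 1)
  attr(res, "best_threshold") <- best
  res
}
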