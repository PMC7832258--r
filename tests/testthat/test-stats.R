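test_that("paired t-test reproduces the textbook worked example", {
  r <- paired_t_test(c(1, 2, 3), c(2, 3, 5))
  expect_equal(r$statistic, 4)
  expect_equal(r$df, 2)
  expect_equal(r$p_value, 2 * stats::pt(-4, 2), tolerance = 1e-12)
  expect_equal(r$p_value, 0.0572, tolerance = 1e-3)
})

test_that("paired t-test matches the reference implementation on random data", {
  set.seed(101)
  for (i in 1:100) {
    n <- sample(2:50, 1)
    x <- stats::rnorm(n, sd = stats::runif(1, 0.5, 3))
    y <- x + stats::rnorm(n, mean = stats::runif(1, -1, 1))
    ours <- paired_t_test(x, y)
    ref <- stats::t.test(y, x, paired = TRUE)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
    expect_equal(ours$df, unname(ref$parameter))
  }
})

test_that("degenerate differences and swapped arguments behave as specified", {
  x <- c(1, 4, 2, 8, 5)
  expect_error(paired_t_test(x, x + 3), class = "dopplervti_error_degenerate")
  expect_error(paired_t_test(x, x), class = "dopplervti_error_degenerate")
  y <- x + stats::rnorm(5)
  a <- paired_t_test(x, y)
  b <- paired_t_test(y, x)
  expect_equal(a$statistic, -b$statistic)
  expect_equal(a$p_value, b$p_value)
})

test_that("detection metrics count the worked confusion examples correctly", {
  m <- detection_metrics(c(TRUE, TRUE, FALSE, FALSE), c(-15, -12, -3, 5),
                         10, "fall")
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  expect_gt(m$separation_margin, 0)
  m2 <- detection_metrics(c(TRUE, FALSE), c(-5, -20), 10, "fall")
  expect_equal(m2$sensitivity, 0)
  expect_equal(m2$specificity, 0)
  # empty positive class: sensitivity is missing, not zero
  m3 <- detection_metrics(c(FALSE, FALSE), c(-5, 2), 10, "fall")
  expect_true(is.na(m3$sensitivity))
  expect_equal(m3$specificity, 1)
})

test_that("detection metrics agree with brute-force confusion counts", {
  set.seed(202)
  for (i in 1:1000) {
    n <- sample(2:30, 1)
    truth <- stats::runif(n) < 0.5
    pred <- stats::rnorm(n, sd = 15)
    th <- stats::runif(1, 0, 20)
    dir <- sample(c("fall", "rise"), 1)
    m <- detection_metrics(truth, pred, th, dir)
    called <- if (dir == "fall") pred <= -th else pred >= th
    tp <- 0L; fn <- 0L; tn <- 0L; fp <- 0L
    for (j in seq_len(n)) {
      if (truth[j] && called[j]) tp <- tp + 1L
      if (truth[j] && !called[j]) fn <- fn + 1L
      if (!truth[j] && !called[j]) tn <- tn + 1L
      if (!truth[j] && called[j]) fp <- fp + 1L
    }
    expect_identical(c(m$tp, m$fn, m$tn, m$fp), c(tp, fn, tn, fp))
    if (tp + fn > 0) expect_equal(m$sensitivity, tp / (tp + fn))
    if (tn + fp > 0) expect_equal(m$specificity, tn / (tn + fp))
  }
})

test_that("raising a fall threshold never increases sensitivity", {
  set.seed(303)
  truth <- stats::runif(25) < 0.5
  pred <- stats::rnorm(25, mean = ifelse(truth, -20, 0), sd = 8)
  sens <- vapply(seq(0, 40, 2), function(th) {
    detection_metrics(truth, pred, th, "fall")$sensitivity
  }, numeric(1))
  expect_true(all(diff(sens) <= 1e-12))
})

test_that("threshold sweeps find perfect separation exactly when it exists", {
  truth <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  sep <- sweep_thresholds(truth, c(-30, -25, -18, -5, 3), "fall")
  expect_true(attr(sep, "perfect_separation"))
  best <- attr(sep, "best_threshold")
  m <- detection_metrics(truth, c(-30, -25, -18, -5, 3), best, "fall")
  expect_equal(m$sensitivity + m$specificity, 2)

  overlapping <- sweep_thresholds(c(TRUE, FALSE), c(-10, -10), "fall")
  expect_false(attr(overlapping, "perfect_separation"))
  expect_error(sweep_thresholds(c(TRUE, TRUE), c(-1, -2), "fall"),
               class = "dopplervti_error_input")
})
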