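test_that("confusion counts follow the 2x2 definitions", {
  n <- 40; k <- 7
  act <- rep(c(TRUE, FALSE), c(k, n - k))
  cc <- confusion(act, act)
  expect_equal(unlist(cc[c("tp", "tn", "fp", "fn")]), c(tp = k, tn = n - k, fp = 0, fn = 0))
  all_pred <- confusion(rep(TRUE, n), rep(FALSE, n))
  expect_equal(all_pred$fp, n)
  expect_error(confusion(c(TRUE, FALSE), TRUE), "length mismatch")
  expect_error(confusion(logical(), logical()), "empty")
  expect_error(confusion_counts(1, -1, 0, 0), "non-negative")

  # label vectors engineered to reproduce the calibration quadruple
  pred <- rep(c(TRUE, FALSE, FALSE), c(45, 709, 17))
  act2 <- rep(c(TRUE, FALSE, TRUE), c(45, 709, 17))
  cal <- confusion(pred, act2)
  expect_equal(unlist(cal[c("tp", "tn", "fp", "fn")]),
               c(tp = 45, tn = 709, fp = 0, fn = 17))
})

test_that("ROC metrics reproduce the published phantom-validation table", {
  ref <- roc_reference_counts()
  # published accuracy / NPV percentages, one row per (case, margin)
  published <- rbind(
    c("calibration", 0, 97.8, 97.7), c("calibration", 3, 100, 100),
    c("calibration", 5, 98.4, 100),
    c("right_post", 0, 99.4, 99.4), c("right_post", 3, 98.5, 100),
    c("right_post", 5, 97.1, 100),
    c("right_ant", 0, 98.8, 98.8), c("right_ant", 3, 98.7, 100),
    c("right_ant", 5, 95.3, 100),
    c("left_post", 0, 99.2, 99.2), c("left_post", 3, 98.2, 100),
    c("left_post", 5, 96.8, 100),
    c("left_ant", 0, 99.0, 99.0), c("left_ant", 3, 97.6, 100),
    c("left_ant", 5, 94.2, 100))
  for (i in seq_len(nrow(published))) {
    row <- ref[ref$case == published[i, 1] &
                 ref$margin_cm == as.numeric(published[i, 2]), ]
    m <- roc_metrics(confusion_counts(row$tp, row$tn, row$fp, row$fn))
    expect_equal(m$accuracy_pct, as.numeric(published[i, 3]),
                 info = paste(published[i, 1:2], collapse = "/"))
    expect_equal(m$npv_pct, as.numeric(published[i, 4]),
                 info = paste(published[i, 1:2], collapse = "/"))
  }
  # NPV is exactly unity whenever there are no false negatives
  m5 <- roc_metrics(confusion_counts(62, 697, 12, 0))
  expect_identical(m5$npv, 1)
  # 100% sensitivity at margins that eliminate false negatives
  expect_identical(roc_metrics(confusion_counts(11, 643, 40, 0))$sensitivity, 1)
})

test_that("ROC metrics error on undefined denominators", {
  expect_error(roc_metrics(confusion_counts(1, 0, 0, 0)), "npv undefined")
  expect_error(roc_metrics(confusion_counts(0, 5, 1, 0)), "sensitivity undefined")
  expect_error(roc_metrics(confusion_counts(0, 0, 0, 0)), "total")
  ok <- roc_metrics(confusion_counts(1, 1, 0, 0))
  expect_equal(ok$accuracy, 1)
})

test_that("measurement simulation is seeded, censored, and moment-faithful", {
  expect_identical(simulate_measurement(c(5, 7), sd_cm = 0, bias_cm = 0), c(5, 7))
  d1 <- simulate_measurement(rep(10, 50), seed = 42)
  d2 <- simulate_measurement(rep(10, 50), seed = 42)
  expect_identical(d1, d2)
  expect_true(all(simulate_measurement(rep(0.1, 200), seed = 1) >= 0))

  draws <- simulate_measurement(rep(100, 1e5), bias_cm = -0.2, sd_cm = 0.7,
                                seed = 7) - 100
  expect_lt(abs(mean(draws) - (-0.2)), 0.01)
  expect_lt(abs(sd(draws) / 0.7 - 1), 0.01)
  # truncation bounds the worst case
  tr <- simulate_measurement(rep(100, 1e4), bias_cm = -0.2, sd_cm = 0.7,
                             max_abs_error_cm = 2.9, seed = 8) - 100
  expect_lte(max(abs(tr)), 2.9)
})

test_that("margin sweeps are monotone and saturate correctly", {
  set.seed(19)
  n <- 702
  calc <- c(rep(0, 40), runif(n - 40, 0.5, 30))
  meas <- simulate_measurement(calc, bias_cm = -0.2, sd_cm = 0.7,
                               max_abs_error_cm = 2.9)
  cmp <- clearance_comparison(rep(couch_sweep_angles(), length.out = n),
                              rep(seq(0, 355, 5), each = 13)[1:n], meas, calc)
  sweep <- margin_sweep(cmp, margins = c(0, 1, 1.5, 3, 5, 10, 50))
  expect_true(all(diff(sweep$fp) >= 0))
  expect_true(all(diff(sweep$fn) <= 0))
  expect_true(all(diff(sweep$tp + sweep$fp) >= 0))  # predicted positives grow
  # margin beyond every calculated distance: perfect sensitivity, no specificity
  last <- sweep[nrow(sweep), ]
  expect_equal(last$sensitivity, 1)
  expect_equal(last$specificity, 0)
  # perfect predictions at margin 0 when measurement equals calculation
  perfect <- clearance_comparison(1:9, 1:9, 2:10, 2:10)
  s0 <- margin_sweep(perfect, margins = 0)
  expect_equal(s0$fp, 0)
  expect_equal(s0$fn, 0)
  expect_error(margin_sweep(cmp[0, ], 5), "empty")
})

test_that("a 3 cm margin eliminates false negatives under the error model", {
  # worst-case-bounded error (|error| <= 2.9 cm): any physical contact implies
  # a calculated distance below 2.9, so fn = 0 at a 3 cm margin, every seed
  for (seed in 1:100) {
    set.seed(seed)
    n <- 200
    calc <- c(rep(0, 15), runif(n - 15, 0, 25))
    meas <- simulate_measurement(calc, bias_cm = -0.2, sd_cm = 0.7,
                                 max_abs_error_cm = 2.9)
    cmp <- clearance_comparison(seq_len(n), rep(0, n), meas, calc)
    sw <- margin_sweep(cmp, margins = c(0, 3, 5))
    expect_equal(sw$fn[sw$margin_cm == 3], 0)
    expect_equal(sw$fn[sw$margin_cm == 5], 0)
  }
})

test_that("difference statistics summarize measured minus calculated", {
  same <- clearance_comparison(c(0, 0, 15, 15), c(0, 5, 0, 5),
                               c(3, 4, 5, 6), c(3, 4, 5, 6))
  s <- difference_stats(same)
  expect_equal(c(s$mean_cm, s$sd_cm, s$min_cm, s$max_cm), c(0, 0, 0, 0))

  shifted <- clearance_comparison(c(0, 0, 15), c(0, 5, 0),
                                  c(4, 5, 6), c(3, 4, 5))
  s1 <- difference_stats(shifted)
  expect_equal(s1$mean_cm, 1)
  expect_equal(s1$sd_cm, 0)
  expect_equal(s1$per_gantry$median_cm, c(1, 1))

  # CLT check on the error model over the full 702-pose design
  hits <- 0L
  for (seed in 1:30) {
    set.seed(seed)
    calc <- runif(702, 3, 30)
    meas <- calc + rnorm(702, -0.2, 0.7)
    cmp <- clearance_comparison(seq_len(702), rep(seq(0, 355, 5), length.out = 702),
                                pmax(meas, 0), calc)
    if (abs(difference_stats(cmp)$mean_cm - (-0.2)) <= 0.08) hits <- hits + 1L
  }
  expect_gte(hits, 27L)  # ~95% coverage band holds across seeds
  expect_error(difference_stats(same[1, ]), ">= 2")
  expect_error(clearance_comparison(c(0, 0), c(5, 5), 1:2, 1:2), "duplicate")
})
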