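# Safety-margin validation: confusion-matrix construction, ROC metrics
# (accuracy, NPV, sensitivity, false positive rate), margin sweeps comparing
# predicted clearances against (possibly simulated) physical measurements, and
# summary statistics of measured-minus-calculated differences.

# half-up rounding, matching how the metric tables print percentages
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Confusion counts for collision prediction
#'
#' The 2x2 categories: TP = predicted and physically colliding, TN = neither,
#' FP = predicted only, FN = physically colliding but not predicted (the
#' safety-critical cell).
#'
#' @param predicted_collision,actual_collision Logical vectors of equal
#'   length (>= 1).
#' @return A list of class `confusion_counts` with integer `tp`, `tn`, `fp`,
#'   `fn`.
#' @export
confusion <- function(predicted_collision, actual_collision) {
  if (length(predicted_collision) != length(actual_collision))
    stop("length mismatch between predicted and actual labels")
  if (length(predicted_collision) < 1L) stop("empty label vectors")
  p <- as.logical(predicted_collision); a <- as.logical(actual_collision)
  if (anyNA(p) || anyNA(a)) stop("NA labels")
  confusion_counts(sum(p & a), sum(!p & !a), sum(p & !a), sum(!p & a))
}

#' @rdname confusion
#' @param tp,tn,fp,fn Non-negative integer counts.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  cc <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (length(cc) != 4L || any(cc < 0) || any(cc != round(cc)))
    stop("counts must be non-negative integers")
  structure(list(tp = as.integer(tp), tn = as.integer(tn),
                 fp = as.integer(fp), fn = as.integer(fn)),
            class = "confusion_counts")
}

#' ROC metrics from confusion counts
#'
#' Accuracy is `(TP + TN) / total`; negative predictive value is
#' `TN / (TN + FN)`, which is exactly 1 whenever there are no false negatives;
#' sensitivity is `TP / (TP + FN)`; the false positive rate is
#' `FP / (FP + TN)`. Percentages are reported rounded half-up to one decimal,
#' the convention of the validation tables.
#'
#' @param c A `confusion_counts` object.
#' @return A list of class `roc_point`: the counts, the rates as fractions
#'   (`accuracy`, `npv`, `sensitivity`, `specificity`, `fpr`), and
#'   `accuracy_pct`, `npv_pct`, `sensitivity_pct` rounded to 1 decimal.
#' @export
roc_metrics <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  total <- c$tp + c$tn + c$fp + c$fn
  if (total <= 0L) stop("metrics undefined: total count is zero")
  if (c$tn + c$fn == 0L) stop("npv undefined: tn + fn = 0")
  if (c$tp + c$fn == 0L) stop("sensitivity undefined: tp + fn = 0")
  acc <- (c$tp + c$tn) / total
  npv <- c$tn / (c$tn + c$fn)
  sens <- c$tp / (c$tp + c$fn)
  fpr <- if (c$fp + c$tn > 0L) c$fp / (c$fp + c$tn) else NA_real_
  spec <- if (is.na(fpr)) NA_real_ else 1 - fpr
  structure(list(tp = c$tp, tn = c$tn, fp = c$fp, fn = c$fn,
                 accuracy = acc, npv = npv, sensitivity = sens,
                 specificity = spec, fpr = fpr,
                 accuracy_pct = round_half_up(100 * acc),
                 npv_pct = round_half_up(100 * npv),
                 sensitivity_pct = round_half_up(100 * sens)),
            class = "roc_point")
}

#' @export
print.roc_point <- function(x, ...) {
  cat(sprintf("TP %d | TN %d | FP %d | FN %d  accuracy %.1f%%  NPV %.1f%%  sensitivity %.1f%%\n",
              x$tp, x$tn, x$fp, x$fn, x$accuracy_pct, x$npv_pct, x$sensitivity_pct))
  invisible(x)
}

#' Simulate a physical clearance measurement
#'
#' Stands in for caliper measurement of the true minimum distance: adds a
#' Gaussian error (optionally truncated to a worst-case magnitude) and censors
#' at zero, since a caliper cannot read a negative clearance — contact reads
#' zero. Deterministic for a fixed seed.
#'
#' @param true_distance_cm Vector of true clearances, cm.
#' @param bias_cm Mean measurement error (measured minus true), cm.
#' @param sd_cm Error standard deviation, cm (>= 0).
#' @param max_abs_error_cm Truncation bound on the error magnitude, cm
#'   (`Inf` for a plain Gaussian).
#' @param seed Optional integer seed set before drawing.
#' @return Vector of simulated measured distances, cm (>= 0).
#' @export
simulate_measurement <- function(true_distance_cm, bias_cm = -0.2, sd_cm = 0.7,
                                 max_abs_error_cm = Inf, seed = NULL) {
  if (sd_cm < 0) stop("sd_cm must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  n <- length(true_distance_cm)
  if (sd_cm == 0) {
    err <- rep(bias_cm, n)
  } else {
    plo <- pnorm(-max_abs_error_cm, bias_cm, sd_cm)
    phi <- pnorm(max_abs_error_cm, bias_cm, sd_cm)
    err <- qnorm(runif(n, plo, phi), bias_cm, sd_cm)
  }
  pmax(0, true_distance_cm + err)
}

#' Build a measured-vs-calculated clearance comparison table
#'
#' @param couch_deg,gantry_deg Pose angles (the pose pairs must be unique).
#' @param measured_cm,calculated_cm Measured and calculated clearances, cm.
#' @return A data frame of class `clearance_comparison` with an added
#'   `difference_cm = measured_cm - calculated_cm` column (negative values
#'   mean the calculation overpredicted the clearance — the dangerous
#'   direction).
#' @export
clearance_comparison <- function(couch_deg, gantry_deg, measured_cm, calculated_cm) {
  df <- data.frame(couch_deg = couch_deg, gantry_deg = gantry_deg,
                   measured_cm = measured_cm, calculated_cm = calculated_cm)
  if (anyDuplicated(df[, c("couch_deg", "gantry_deg")]))
    stop("duplicate (couch, gantry) poses in comparison")
  df$difference_cm <- df$measured_cm - df$calculated_cm
  class(df) <- c("clearance_comparison", class(df))
  df
}

#' ROC margin sweep over a clearance comparison
#'
#' For each safety margin, predicted collision is `calculated < margin` and
#' actual collision is `measured <= physical_clearance_threshold` (default 0:
#' physical contact — a censored-at-zero measurement reads exactly 0 on
#' contact, so the threshold is inclusive). Rates with undefined denominators
#' are `NA` rather than errors, since saturated margins are expected points on
#' a sweep.
#'
#' @param comparison A `clearance_comparison`.
#' @param margins Numeric vector of margins to sweep, cm.
#' @param physical_clearance_threshold Measured distance at or below which a
#'   pose counts as a physical collision, cm.
#' @return A data frame, one row per margin: counts, `sensitivity`,
#'   `specificity`, `fpr`, `accuracy`, `npv` (fractions).
#' @export
margin_sweep <- function(comparison, margins,
                         physical_clearance_threshold = 0) {
  stopifnot(inherits(comparison, "clearance_comparison"))
  if (nrow(comparison) == 0L) stop("empty comparison")
  actual <- comparison$measured_cm <= physical_clearance_threshold
  rows <- lapply(sort(margins), function(m) {
    pred <- comparison$calculated_cm < m
    tp <- sum(pred & actual); tn <- sum(!pred & !actual)
    fp <- sum(pred & !actual); fn <- sum(!pred & actual)
    total <- tp + tn + fp + fn
    data.frame(margin_cm = m, tp = tp, tn = tn, fp = fp, fn = fn,
               sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               specificity = if (fp + tn > 0) tn / (fp + tn) else NA_real_,
               fpr = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
               accuracy = (tp + tn) / total,
               npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Summary statistics of measured-minus-calculated differences
#'
#' Population statistics of the per-pose difference plus a per-gantry-angle
#' min/median/max aggregation across couch angles (the radial-plot summary).
#'
#' @param comparison A `clearance_comparison` with >= 2 poses.
#' @return A list: `mean_cm`, `sd_cm`, `min_cm`, `max_cm`, and `per_gantry`
#'   (data frame `gantry_deg`, `min_cm`, `median_cm`, `max_cm`).
#' @export
difference_stats <- function(comparison) {
  stopifnot(inherits(comparison, "clearance_comparison"))
  if (nrow(comparison) < 2L) stop("need >= 2 poses for a standard deviation")
  d <- comparison$difference_cm
  ag <- aggregate(difference_cm ~ gantry_deg, data = comparison,
                  FUN = function(v) c(min = min(v), median = median(v),
                                      max = max(v)))
  per_gantry <- data.frame(gantry_deg = ag$gantry_deg,
                           min_cm = ag$difference_cm[, "min"],
                           median_cm = ag$difference_cm[, "median"],
                           max_cm = ag$difference_cm[, "max"])
  list(mean_cm = mean(d), sd_cm = sd(d), min_cm = min(d), max_cm = max(d),
       per_gantry = per_gantry[order(per_gantry$gantry_deg), ])
}
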