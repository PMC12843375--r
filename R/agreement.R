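# Method-agreement statistics between automated and manual angles:
# Pearson r, ICC(A,1) (two-way model, absolute agreement, single
# measurement, McGraw-Wong taxonomy) with F-based 95% CI, Lin's CCC,
# error metrics, and Bland-Altman limits of agreement.

#' Read a paired-angle CSV
#'
#' Columns `scan_id`, `automated_deg`, `manual_deg`; header required.
#' Rows with a missing value in either angle column are dropped.
#'
#' @param path CSV path.
#' @return Data frame with the three columns.
#' @export
read_paired_angles <- function(path) {
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) abort(sprintf("cannot parse paired CSV: %s",
                                                   conditionMessage(e)),
                                           "parse_error"))
  need <- c("scan_id", "automated_deg", "manual_deg")
  if (!all(need %in% names(df))) {
    abort(sprintf("paired CSV must have columns %s", paste(need, collapse = ", ")),
          "parse_error")
  }
  df <- df[stats::complete.cases(df[, c("automated_deg", "manual_deg")]), need]
  rownames(df) <- NULL
  df
}

check_pairs <- function(pairs, min_n = 3L) {
  if (!all(c("automated_deg", "manual_deg") %in% names(pairs))) {
    abort("pairs must have columns automated_deg and manual_deg", "parse_error")
  }
  pairs <- pairs[stats::complete.cases(pairs[, c("automated_deg", "manual_deg")]), ,
                 drop = FALSE]
  if (nrow(pairs) < min_n) {
    abort(sprintf("need at least %d complete pairs, got %d", min_n, nrow(pairs)),
          "too_few_pairs_error")
  }
  pairs
}

# ICC(A,1): two-way model, absolute agreement, single measurement.
# Mean-squares formulation with the standard F-distribution CI bounds.
icc_a1 <- function(x, y, conf_level = 0.95) {
  X <- cbind(x, y)
  n <- nrow(X); k <- 2
  mu <- mean(X)
  rm <- rowMeans(X); cm <- colMeans(X)
  SSR <- k * sum((rm - mu)^2)
  SSC <- n * sum((cm - mu)^2)
  SSE <- sum((X - mu)^2) - SSR - SSC
  MSR <- SSR / (n - 1); MSC <- SSC / (k - 1); MSE <- SSE / ((n - 1) * (k - 1))
  icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))

  alpha <- 1 - conf_level
  if (MSE <= 0 && MSC <= 0) {
    ci <- c(1, 1)  # perfect agreement: no rater or residual variance
  } else {
    Fj <- MSC / MSE
    vn <- (k - 1) * (n - 1) * (k * icc * Fj + n * (1 + (k - 1) * icc) - k * icc)^2
    vd <- (n - 1) * k^2 * icc^2 * Fj^2 + (n * (1 + (k - 1) * icc) - k * icc)^2
    v <- vn / vd
    FL <- stats::qf(1 - alpha / 2, n - 1, v)
    FU <- stats::qf(1 - alpha / 2, v, n - 1)
    lower <- n * (MSR - FL * MSE) / (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
    upper <- n * (FU * MSR - MSE) / (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
    ci <- c(lower, upper)
  }
  list(icc = icc, ci = ci)
}

# Lin's concordance correlation, population (n-denominator) moments.
lins_ccc <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2); sy2 <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  2 * sxy / (sx2 + sy2 + (mx - my)^2)
}

#' Agreement statistics between automated and manual angles
#'
#' Differences are taken automated minus manual. Limits of agreement are
#' mean difference +/- 1.96 SD (sample SD, n-1 denominator); the 95th
#' percentile of the absolute error uses the linear-interpolation
#' quantile (type 7).
#'
#' @param pairs Data frame with columns `automated_deg` and `manual_deg`
#'   (n >= 3; both columns need nonzero variance).
#' @param conf_level Confidence level for the ICC interval.
#' @return Object of class `agreement_report` with fields `n`,
#'   `pearson_r`, `icc_a1`, `icc_ci`, `ccc`, `rmse_deg`, `mse_deg2`,
#'   `mae_deg`, `median_ae_deg`, `p95_ae_deg`, `ba_mean_diff_deg`,
#'   `ba_loa_low_deg`, `ba_loa_high_deg`.
#' @export
agreement_stats <- function(pairs, conf_level = 0.95) {
  pairs <- check_pairs(pairs, 3L)
  x <- pairs$automated_deg; y <- pairs$manual_deg
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("zero variance in an angle column; r/ICC/CCC undefined",
          "zero_variance_error")
  }
  d <- x - y
  icc <- icc_a1(x, y, conf_level)
  ad <- abs(d)
  sd_d <- stats::sd(d)
  structure(list(n = length(x),
                 pearson_r = stats::cor(x, y),
                 icc_a1 = icc$icc,
                 icc_ci = icc$ci,
                 ccc = lins_ccc(x, y),
                 rmse_deg = sqrt(mean(d^2)),
                 mse_deg2 = mean(d^2),
                 mae_deg = mean(ad),
                 median_ae_deg = stats::median(ad),
                 p95_ae_deg = unname(stats::quantile(ad, 0.95, type = 7)),
                 ba_mean_diff_deg = mean(d),
                 ba_loa_low_deg = mean(d) - 1.96 * sd_d,
                 ba_loa_high_deg = mean(d) + 1.96 * sd_d),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Agreement over %d pairs (automated - manual):\n", x$n))
  cat(sprintf("  r = %.3f  ICC(A,1) = %.3f (95%% CI %.3f-%.3f)  CCC = %.3f\n",
              x$pearson_r, x$icc_a1, x$icc_ci[1], x$icc_ci[2], x$ccc))
  cat(sprintf("  RMSE %.2f deg (MSE %.2f)  MAE %.2f  median AE %.2f  95th pct AE %.2f\n",
              x$rmse_deg, x$mse_deg2, x$mae_deg, x$median_ae_deg, x$p95_ae_deg))
  cat(sprintf("  Bland-Altman: mean diff %.2f deg, LoA [%.2f, %.2f]\n",
              x$ba_mean_diff_deg, x$ba_loa_low_deg, x$ba_loa_high_deg))
  invisible(x)
}

#' Wilson score confidence interval for a proportion
#'
#' @param k Number of successes.
#' @param n Number of trials (> 0).
#' @param conf_level Confidence level.
#' @return Numeric `c(lower, upper)` in `[0, 1]`.
#' @export
wilson_ci <- function(k, n, conf_level = 0.95) {
  stopifnot(n > 0, k >= 0, k <= n)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, centre - half), min(1, centre + half))
}

#' ROC area under the curve by the trapezoidal rule
#'
#' Sweeps all unique score thresholds (ties grouped) and integrates the
#' resulting ROC polygon. A constant score yields 0.5.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Logical or 0/1 condition-positive labels.
#' @return AUC in `[0, 1]`, `NA` if either class is empty.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  thr <- sort(unique(scores), decreasing = TRUE)
  tprs <- c(0, vapply(thr, function(t) sum(scores >= t & labels) / n_pos, numeric(1)))
  fprs <- c(0, vapply(thr, function(t) sum(scores >= t & !labels) / n_neg, numeric(1)))
  sum(diff(fprs) * (utils::head(tprs, -1) + utils::tail(tprs, -1)) / 2)
}

diagnostic_report <- function(tp, fp, fn, tn, auc = NA_real_,
                              conf_level = 0.95) {
  n <- tp + fp + fn + tn
  if (n < 1) abort("empty confusion matrix", "too_few_pairs_error")
  metric <- function(num, den) {
    if (den == 0) return(list(est = NA_real_, ci = c(NA_real_, NA_real_)))
    list(est = num / den, ci = wilson_ci(num, den, conf_level))
  }
  sens <- metric(tp, tp + fn)
  spec <- metric(tn, tn + fp)
  ppv <- metric(tp, tp + fp)
  npv <- metric(tn, tn + fn)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn, n = n,
                 sensitivity = sens$est, sensitivity_ci = sens$ci,
                 specificity = spec$est, specificity_ci = spec$ci,
                 ppv = ppv$est, ppv_ci = ppv$ci,
                 npv = npv$est, npv_ci = npv$ci,
                 prevalence = (tp + fn) / n,
                 auc = auc),
            class = "diagnostic_report")
}

#' Threshold diagnostics of automated vs manual classification
#'
#' The manual angle defines the reference class (manual >= threshold is
#' condition-positive); the automated angle is thresholded the same way
#' to build the 2x2 table. Proportions carry Wilson score CIs; metrics
#' with a zero denominator are reported as `NA`, not 0. The AUC comes
#' from the ROC of the continuous automated angle against the binary
#' manual label.
#'
#' @param pairs Data frame with `automated_deg` and `manual_deg` columns.
#' @param threshold_deg Classification threshold in degrees (default 40).
#' @param conf_level Confidence level for the Wilson intervals.
#' @return Object of class `diagnostic_report`.
#' @export
diagnostics_at_threshold <- function(pairs, threshold_deg = 40,
                                     conf_level = 0.95) {
  pairs <- check_pairs(pairs, 1L)
  auto_pos <- pairs$automated_deg >= threshold_deg
  man_pos <- pairs$manual_deg >= threshold_deg
  rep <- diagnostic_report(tp = sum(auto_pos & man_pos),
                           fp = sum(auto_pos & !man_pos),
                           fn = sum(!auto_pos & man_pos),
                           tn = sum(!auto_pos & !man_pos),
                           auc = roc_auc(pairs$automated_deg, man_pos),
                           conf_level = conf_level)
  rep
}

#' Diagnostics from printed confusion-matrix counts
#'
#' Entry point for published 2x2 tables where no angle data are
#' available; identical to [diagnostics_at_threshold()] minus the AUC.
#'
#' @param tp,fp,fn,tn Nonnegative integer counts, sum >= 1.
#' @param conf_level Confidence level for the Wilson intervals.
#' @return Object of class `diagnostic_report` (AUC is `NA`).
#' @export
#' @examples
#' confusion_from_counts(63, 11, 5, 101)
confusion_from_counts <- function(tp, fp, fn, tn, conf_level = 0.95) {
  counts <- c(tp, fp, fn, tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("counts must be nonnegative integers", "parse_error")
  }
  diagnostic_report(tp, fp, fn, tn, conf_level = conf_level)
}

#' @export
print.diagnostic_report <- function(x, ...) {
  pct <- function(p) if (is.na(p)) "NA" else sprintf("%.0f%%", 100 * p)
  ci <- function(ci) if (anyNA(ci)) "" else sprintf(" (95%% CI %.0f-%.0f%%)",
                                                    100 * ci[1], 100 * ci[2])
  cat(sprintf("Confusion matrix (n = %d): TP %d  FP %d  FN %d  TN %d\n",
              x$n, x$tp, x$fp, x$fn, x$tn))
  cat(sprintf("  sensitivity %s%s  specificity %s%s\n",
              pct(x$sensitivity), ci(x$sensitivity_ci),
              pct(x$specificity), ci(x$specificity_ci)))
  cat(sprintf("  PPV %s%s  NPV %s%s  prevalence %s\n",
              pct(x$ppv), ci(x$ppv_ci), pct(x$npv), ci(x$npv_ci),
              pct(x$prevalence)))
  if (!is.na(x$auc)) cat(sprintf("  AUC %.2f\n", x$auc))
  invisible(x)
}

agreement_report_as_list <- function(x) {
  list(n = x$n, pearson_r = x$pearson_r,
       icc_a1 = x$icc_a1, icc_ci_low = x$icc_ci[1], icc_ci_high = x$icc_ci[2],
       ccc = x$ccc, rmse_deg = x$rmse_deg, mse_deg2 = x$mse_deg2,
       mae_deg = x$mae_deg, median_ae_deg = x$median_ae_deg,
       p95_ae_deg = x$p95_ae_deg,
       ba_mean_diff_deg = x$ba_mean_diff_deg,
       ba_loa_low_deg = x$ba_loa_low_deg,
       ba_loa_high_deg = x$ba_loa_high_deg)
}

diagnostic_report_as_list <- function(x) {
  list(tp = x$tp, fp = x$fp, fn = x$fn, tn = x$tn, n = x$n,
       sensitivity = x$sensitivity,
       sensitivity_ci = as.list(x$sensitivity_ci),
       specificity = x$specificity,
       specificity_ci = as.list(x$specificity_ci),
       ppv = x$ppv, ppv_ci = as.list(x$ppv_ci),
       npv = x$npv, npv_ci = as.list(x$npv_ci),
       prevalence = x$prevalence, auc = x$auc)
}

#' Write agreement and/or diagnostic reports as JSON
#'
#' @param reports Named list whose elements are `agreement_report`,
#'   `diagnostic_report` or `detection_eval_report` objects.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(reports, path) {
  payload <- lapply(reports, function(x) {
    if (inherits(x, "agreement_report")) agreement_report_as_list(x)
    else if (inherits(x, "diagnostic_report")) diagnostic_report_as_list(x)
    else if (inherits(x, "detection_eval_report")) detection_report_as_list(x)
    else x
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
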