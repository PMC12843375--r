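# Detection evaluation: pooled and per-level precision/recall/F1, mean
# IoU of matched pairs, AP@0.5 and AP averaged over IoU thresholds
# 0.50:0.05:0.95 with 101-point interpolated precision-recall
# integration (the convention the mAP metric names come from).

# Pool (confidence, is-TP) flags across a dataset at one IoU threshold.
pooled_pr_flags <- function(dataset, iou_threshold) {
  conf <- numeric(0); tp <- logical(0); n_truth <- 0L
  for (pair in dataset) {
    m <- match_detections(pair$pred, pair$truth, iou_threshold)
    conf <- c(conf, pair$pred$confidence)
    tp <- c(tp, m$pred_outcome == "TP")
    n_truth <- n_truth + length(m$truth_kept)
  }
  list(conf = conf, tp = tp, n_truth = n_truth)
}

# 101-point interpolated average precision.
average_precision <- function(conf, tp, n_truth) {
  if (n_truth == 0L) return(NA_real_)
  if (!length(conf)) return(0)
  ord <- order(-conf)
  tp <- tp[ord]
  cum_tp <- cumsum(tp)
  cum_fp <- cumsum(!tp)
  recall <- cum_tp / n_truth
  precision <- cum_tp / (cum_tp + cum_fp)
  # precision envelope: max precision at recall >= r
  r_grid <- seq(0, 1, by = 0.01)
  p_interp <- vapply(r_grid, function(r) {
    ok <- recall >= r - 1e-12
    if (any(ok)) max(precision[ok]) else 0
  }, numeric(1))
  mean(p_interp)
}

#' Evaluate detections over a dataset
#'
#' @param dataset List of per-image pairs, each a list with elements
#'   `pred` and `truth` ([bounding_boxes()] tables).
#' @param iou_threshold IoU criterion for the precision/recall/F1 and
#'   mean-IoU summaries (default 0.5).
#' @return Object of class `detection_eval_report`: list with pooled
#'   `precision`, `recall`, `f1`, `ap50`, `ap50_95`, `mean_iou`,
#'   `sd_iou`, counts `tp`/`fp`/`fn`, `n_images`, `image_success_rate`,
#'   and `per_level` (data frame with per-level recall, missed counts and
#'   mean IoU from the truth side, plus precision where predictions carry
#'   level labels).
#' @export
evaluate_detections <- function(dataset, iou_threshold = 0.5) {
  if (!length(dataset)) abort("empty detection dataset", "empty_dataset_error")
  levels <- thoracic_levels()
  tp <- fp <- fn <- 0L
  ious <- numeric(0)
  success <- logical(0)
  lvl_tp <- lvl_fn <- stats::setNames(integer(9), levels)
  lvl_pred_tp <- lvl_pred_fp <- stats::setNames(integer(9), levels)
  lvl_iou <- stats::setNames(vector("list", 9), levels)

  for (pair in dataset) {
    m <- match_detections(pair$pred, pair$truth, iou_threshold)
    tp <- tp + sum(m$pred_outcome == "TP")
    fp <- fp + sum(m$pred_outcome == "FP")
    fn <- fn + sum(!m$truth_matched)
    ious <- c(ious, m$matches$iou)
    success <- c(success, m$image_success)

    truth <- pair$truth[m$truth_kept, , drop = FALSE]
    tl <- truth$level
    for (k in seq_along(tl)) {
      if (is.na(tl[k]) || !tl[k] %in% levels) next
      if (m$truth_matched[k]) {
        lvl_tp[tl[k]] <- lvl_tp[tl[k]] + 1L
        mi <- m$matches$iou[m$matches$truth_idx == m$truth_kept[k]]
        lvl_iou[[tl[k]]] <- c(lvl_iou[[tl[k]]], mi)
      } else {
        lvl_fn[tl[k]] <- lvl_fn[tl[k]] + 1L
      }
    }
    pl <- pair$pred$level
    for (k in seq_along(pl)) {
      if (is.na(pl[k]) || !pl[k] %in% levels) next
      if (m$pred_outcome[k] == "TP") {
        lvl_pred_tp[pl[k]] <- lvl_pred_tp[pl[k]] + 1L
      } else {
        lvl_pred_fp[pl[k]] <- lvl_pred_fp[pl[k]] + 1L
      }
    }
  }

  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_

  flags50 <- pooled_pr_flags(dataset, 0.5)
  ap50 <- average_precision(flags50$conf, flags50$tp, flags50$n_truth)
  ap_each <- vapply(seq(0.5, 0.95, by = 0.05), function(t) {
    fl <- pooled_pr_flags(dataset, t)
    average_precision(fl$conf, fl$tp, fl$n_truth)
  }, numeric(1))
  ap50_95 <- mean(ap_each)

  per_level <- data.frame(
    level = levels,
    tp = as.integer(lvl_tp),
    fn = as.integer(lvl_fn),
    missed_count = as.integer(lvl_fn),
    recall = ifelse(lvl_tp + lvl_fn > 0, lvl_tp / (lvl_tp + lvl_fn), NA_real_),
    precision = ifelse(lvl_pred_tp + lvl_pred_fp > 0,
                       lvl_pred_tp / (lvl_pred_tp + lvl_pred_fp), NA_real_),
    mean_iou = vapply(lvl_iou, function(v) if (length(v)) mean(v) else NA_real_,
                      numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  per_level$f1 <- ifelse(!is.na(per_level$precision) & !is.na(per_level$recall) &
                           per_level$precision + per_level$recall > 0,
                         2 * per_level$precision * per_level$recall /
                           (per_level$precision + per_level$recall), NA_real_)

  structure(list(precision = precision, recall = recall, f1 = f1,
                 ap50 = ap50, ap50_95 = ap50_95,
                 mean_iou = if (length(ious)) mean(ious) else NA_real_,
                 sd_iou = if (length(ious) > 1) stats::sd(ious) else NA_real_,
                 tp = tp, fp = fp, fn = fn,
                 n_images = length(dataset),
                 image_success_rate = mean(success),
                 per_level = per_level),
            class = "detection_eval_report")
}

#' @export
print.detection_eval_report <- function(x, ...) {
  cat(sprintf("Detection evaluation over %d image(s):\n", x$n_images))
  cat(sprintf("  precision %.3f  recall %.3f  F1 %.3f\n", x$precision, x$recall, x$f1))
  cat(sprintf("  AP@0.5 %.3f  AP@0.5:0.95 %.3f  mean IoU %.3f +/- %.3f\n",
              x$ap50, x$ap50_95, x$mean_iou,
              if (is.na(x$sd_iou)) 0 else x$sd_iou))
  cat(sprintf("  image-level success rate %.3f\n", x$image_success_rate))
  invisible(x)
}

detection_report_as_list <- function(x) {
  list(precision = x$precision, recall = x$recall, f1 = x$f1,
       map50 = x$ap50, map50_95 = x$ap50_95,
       mean_iou = x$mean_iou, sd_iou = x$sd_iou,
       tp = x$tp, fp = x$fp, fn = x$fn,
       n_images = x$n_images, image_success_rate = x$image_success_rate,
       per_level = x$per_level)
}
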