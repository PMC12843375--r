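# Classical stand-in detector and bounding-box primitives.
#
# Bounding boxes are data frames with columns x_min, y_min, x_max, y_max,
# level (Th4..Th12 or NA when unassigned), confidence in [0, 1], and an
# optional logical `partial` flag on ground-truth boxes (partially visible
# vertebrae are excluded from evaluation).

#' Construct a bounding-box table
#'
#' @param x_min,y_min,x_max,y_max Numeric box edges in pixels
#'   (`x_min < x_max`, `y_min < y_max`).
#' @param level Vertebral level labels or `NA` when unassigned.
#' @param confidence Confidence scores in `[0, 1]`.
#' @param partial Logical; ground-truth boxes flagged partial are excluded
#'   from evaluation.
#' @return Data frame of class `bounding_boxes`.
#' @export
bounding_boxes <- function(x_min, y_min, x_max, y_max,
                           level = NA_character_, confidence = 1,
                           partial = FALSE) {
  n <- length(x_min)
  df <- data.frame(x_min = as.numeric(x_min), y_min = as.numeric(y_min),
                   x_max = as.numeric(x_max), y_max = as.numeric(y_max),
                   level = rep_len(as.character(level), n),
                   confidence = rep_len(as.numeric(confidence), n),
                   partial = rep_len(as.logical(partial), n),
                   stringsAsFactors = FALSE)
  if (n && any(df$x_min >= df$x_max | df$y_min >= df$y_max)) {
    abort("degenerate bounding box: min edge must be below max edge", "box_error")
  }
  class(df) <- c("bounding_boxes", "data.frame")
  df
}

empty_boxes <- function() {
  bounding_boxes(numeric(0), numeric(0), numeric(0), numeric(0))
}

#' Intersection over union of two boxes
#'
#' @param a,b Length-4 numeric vectors `(x_min, y_min, x_max, y_max)` or
#'   single-row box data frames.
#' @return IoU in `[0, 1]`; 0 for disjoint boxes.
#' @export
#' @examples
#' iou(c(0, 0, 2, 2), c(1, 0, 3, 2))  # 1/3
iou <- function(a, b) {
  if (is.data.frame(a)) a <- unlist(a[1, c("x_min", "y_min", "x_max", "y_max")])
  if (is.data.frame(b)) b <- unlist(b[1, c("x_min", "y_min", "x_max", "y_max")])
  a <- as.numeric(a); b <- as.numeric(b)
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  union <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  inter / union
}

# IoU matrix between two box tables (rows of a x rows of b).
iou_matrix <- function(a, b) {
  if (!nrow(a) || !nrow(b)) return(matrix(0, nrow(a), nrow(b)))
  outer(seq_len(nrow(a)), seq_len(nrow(b)),
        Vectorize(function(i, j) iou(unlist(a[i, 1:4]), unlist(b[j, 1:4]))))
}

# Connected-component labelling of a logical mask (4-neighbourhood) by
# iterative minimum-label propagation; adequate for the blob sizes here.
label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  lab[mask] <- seq_len(sum(mask))
  if (!any(mask)) return(lab)
  repeat {
    shifted <- lab
    up <- rbind(lab[-1, , drop = FALSE], Inf)
    dn <- rbind(Inf, lab[-nrow(lab), , drop = FALSE])
    lf <- cbind(lab[, -1, drop = FALSE], Inf)
    rt <- cbind(Inf, lab[, -ncol(lab), drop = FALSE])
    for (nb in list(up, dn, lf, rt)) {
      cand <- nb > 0 & nb < shifted & shifted > 0
      shifted[cand] <- nb[cand]
    }
    if (identical(shifted, lab)) break
    lab <- shifted
  }
  lab
}

#' Detect bright blobs in a phantom image
#'
#' Thresholds the image, extracts 4-connected components, discards those
#' below a minimum area and returns each survivor's tight axis-aligned box
#' with confidence equal to the mean interior intensity. Boxes are sorted
#' cranially (ascending y of box centre); levels Th4..Th12 are assigned by
#' rank only when exactly nine boxes survive, otherwise left unassigned.
#'
#' @param image Numeric matrix with values in `[0, 1]`.
#' @param min_area Minimum component area in pixels.
#' @param intensity_threshold Foreground threshold in `[0, 1]`.
#' @return A [bounding_boxes()] table (empty on a blank image).
#' @export
detect_blobs <- function(image, min_area = 20, intensity_threshold = 0.5) {
  stopifnot(is.matrix(image))
  lab <- label_components(image >= intensity_threshold)
  ids <- setdiff(unique(as.vector(lab)), 0L)
  if (!length(ids)) return(empty_boxes())
  rows <- lapply(ids, function(id) {
    idx <- which(lab == id, arr.ind = TRUE)
    if (nrow(idx) < min_area) return(NULL)
    data.frame(x_min = min(idx[, 2]) - 1, y_min = min(idx[, 1]) - 1,
               x_max = max(idx[, 2]), y_max = max(idx[, 1]),
               confidence = mean(image[idx]))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty_boxes())
  df <- do.call(rbind, rows)
  df <- df[order((df$y_min + df$y_max) / 2), , drop = FALSE]
  lev <- if (nrow(df) == 9) thoracic_levels() else NA_character_
  bounding_boxes(df$x_min, df$y_min, df$x_max, df$y_max,
                 level = lev, confidence = df$confidence)
}

#' Match predicted to ground-truth boxes at an IoU threshold
#'
#' Greedy one-to-one matching by descending prediction confidence: each
#' prediction is matched to the still-unmatched truth box of highest IoU
#' at or above the threshold. Unmatched predictions are false positives,
#' unmatched truths false negatives. Truth boxes flagged `partial` are
#' removed before matching. Image-level success requires every
#' (non-partial) truth box to be matched.
#'
#' @param pred,truth [bounding_boxes()] tables.
#' @param iou_threshold Matching criterion (default 0.5).
#' @return List with `matches` (data frame `pred_idx`, `truth_idx`,
#'   `iou`), `pred_outcome` (`"TP"`/`"FP"` per prediction),
#'   `truth_matched` (logical per retained truth box), `truth_kept`
#'   (indices of non-partial truths) and `image_success`.
#' @export
match_detections <- function(pred, truth, iou_threshold = 0.5) {
  partial <- if (is.null(truth$partial)) rep(FALSE, nrow(truth)) else isTRUE_vec(truth$partial)
  truth_kept <- which(!partial)
  truth <- truth[truth_kept, , drop = FALSE]
  np <- nrow(pred); nt <- nrow(truth)
  pred_outcome <- rep("FP", np)
  truth_matched <- rep(FALSE, nt)
  matches <- data.frame(pred_idx = integer(0), truth_idx = integer(0),
                        iou = numeric(0))
  if (np && nt) {
    M <- iou_matrix(pred, truth)
    ord <- order(-pred$confidence, seq_len(np))
    for (i in ord) {
      avail <- which(!truth_matched)
      if (!length(avail)) break
      best <- avail[which.max(M[i, avail])]
      if (M[i, best] >= iou_threshold) {
        truth_matched[best] <- TRUE
        pred_outcome[i] <- "TP"
        matches <- rbind(matches,
                         data.frame(pred_idx = i,
                                    truth_idx = truth_kept[best],
                                    iou = M[i, best]))
      }
    }
  }
  list(matches = matches, pred_outcome = pred_outcome,
       truth_matched = truth_matched, truth_kept = truth_kept,
       image_success = all(truth_matched))
}

isTRUE_vec <- function(x) {
  if (is.null(x)) logical(0) else !is.na(x) & x
}

#' Write boxes in YOLO annotation format
#'
#' One line per box: `class x_center y_center width height`, all
#' normalised to `[0, 1]` by the image dimensions; class indices 0-8 map
#' to Th4-Th12 (`-1` for unassigned levels).
#'
#' @param boxes A box data frame with columns `level`, `x_min`, `y_min`,
#'   `x_max`, `y_max`.
#' @param path Optional output path; when `NULL` the lines are returned.
#' @param image_size Integer `(width, height)`.
#' @return Character vector of lines (invisibly when written to `path`).
#' @export
write_yolo <- function(boxes, path = NULL, image_size) {
  lines <- yolo_lines(boxes, image_size)
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

yolo_lines <- function(boxes, image_size) {
  w <- image_size[1]; h <- image_size[2]
  cls <- match(boxes$level, thoracic_levels()) - 1L
  cls[is.na(cls)] <- -1L
  sprintf("%d %.9f %.9f %.9f %.9f", cls,
          (boxes$x_min + boxes$x_max) / 2 / w,
          (boxes$y_min + boxes$y_max) / 2 / h,
          (boxes$x_max - boxes$x_min) / w,
          (boxes$y_max - boxes$y_min) / h)
}

#' Read YOLO annotation lines into a box table
#'
#' @param path Annotation file path (or character vector of lines via
#'   `lines`).
#' @param image_size Integer `(width, height)` used to de-normalise.
#' @param lines Optional character vector overriding `path`.
#' @return A [bounding_boxes()] table.
#' @export
read_yolo <- function(path, image_size, lines = NULL) {
  if (is.null(lines)) lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(empty_boxes())
  fields <- do.call(rbind, lapply(strsplit(lines, "\\s+"), as.numeric))
  if (ncol(fields) < 5 || anyNA(fields[, 1:5])) {
    abort("malformed YOLO annotation line", "parse_error")
  }
  w <- image_size[1]; h <- image_size[2]
  cx <- fields[, 2] * w; cy <- fields[, 3] * h
  bw <- fields[, 4] * w; bh <- fields[, 5] * h
  lev <- ifelse(fields[, 1] >= 0 & fields[, 1] <= 8,
                thoracic_levels()[fields[, 1] + 1], NA_character_)
  conf <- if (ncol(fields) >= 6) fields[, 6] else 1
  bounding_boxes(cx - bw / 2, cy - bh / 2, cx + bw / 2, cy + bh / 2,
                 level = lev, confidence = conf)
}
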