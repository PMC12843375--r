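# IoU, matching and the detection-evaluation metrics.

test_that("iou unit cases hold exactly", {
  a <- c(0, 0, 2, 2)
  expect_identical(iou(a, a), 1)
  expect_identical(iou(a, c(5, 5, 6, 6)), 0)
  expect_equal(iou(a, c(1, 0, 3, 2)), 1 / 3, tolerance = 1e-12)
  # symmetry and the <= 1 bound on random boxes
  set.seed(2)
  for (i in 1:50) {
    b1 <- sort(stats::runif(2, 0, 10)); b2 <- sort(stats::runif(2, 0, 10))
    b3 <- sort(stats::runif(2, 0, 10)); b4 <- sort(stats::runif(2, 0, 10))
    x <- c(b1[1], b2[1], b1[2], b2[2]); y <- c(b3[1], b4[1], b3[2], b4[2])
    expect_equal(iou(x, y), iou(y, x), tolerance = 1e-14)
    expect_lte(iou(x, y), 1)
  }
})

test_that("greedy matching follows confidence order and is one-to-one", {
  truth <- bounding_boxes(0, 0, 10, 10)
  # prediction at IoU 0.4: sub-threshold, one FP + one FN
  pred <- bounding_boxes(0, 6, 10, 16)
  expect_equal(iou(unlist(pred[1, 1:4]), unlist(truth[1, 1:4])), 0.25)
  m <- match_detections(pred, truth)
  expect_equal(m$pred_outcome, "FP")
  expect_false(any(m$truth_matched))
  expect_false(m$image_success)

  # two predictions over one truth: the higher-confidence one wins even
  # though its IoU is lower (greedy-by-confidence rule); exhaustively the
  # only admissible one-to-one matchings are {p1-t}, {p2-t}, and greedy
  # picks the confidence-0.9 prediction
  truth1 <- bounding_boxes(0, 0, 10, 10)
  # nested boxes [0,0,10,h] have IoU = h/10 with the truth
  pred2 <- bounding_boxes(c(0, 0), c(0, 0), c(10, 10), c(9, 6),
                          confidence = c(0.8, 0.9))
  m2 <- match_detections(pred2, truth1)
  expect_equal(m2$matches$pred_idx, 2L)
  expect_equal(m2$pred_outcome, c("FP", "TP"))
  expect_equal(sum(m2$pred_outcome == "TP"), sum(m2$truth_matched))

  # perfect detector
  mp <- match_detections(truth, truth)
  expect_equal(mp$pred_outcome, "TP")
  expect_true(mp$image_success)

  # partial truth boxes are excluded from matching and FN counts
  truth_part <- bounding_boxes(c(0, 20), c(0, 20), c(10, 30), c(10, 30),
                               partial = c(FALSE, TRUE))
  mpart <- match_detections(bounding_boxes(0, 0, 10, 10), truth_part)
  expect_true(mpart$image_success)
  expect_equal(length(mpart$truth_matched), 1)
})

test_that("a perfect detector scores 1 on every pooled metric", {
  dataset <- lapply(1:20, perfect_phantom_pair)
  rep <- evaluate_detections(dataset)
  expect_equal(rep$precision, 1)
  expect_equal(rep$recall, 1)
  expect_equal(rep$f1, 1)
  expect_equal(rep$ap50, 1)
  expect_equal(rep$ap50_95, 1)
  expect_equal(rep$mean_iou, 1)
  expect_equal(rep$image_success_rate, 1)
  expect_true(all(rep$per_level$recall == 1))
})

test_that("a detector that always misses Th12 is charged exactly for it", {
  dataset <- lapply(1:10, function(s) {
    pair <- perfect_phantom_pair(s)
    pair$pred <- pair$pred[pair$pred$level != "Th12", ]
    class(pair$pred) <- c("bounding_boxes", "data.frame")
    pair
  })
  rep <- evaluate_detections(dataset)
  pl <- rep$per_level
  expect_equal(pl$recall[pl$level == "Th12"], 0)
  expect_equal(pl$missed_count[pl$level == "Th12"], 10)
  expect_true(all(pl$recall[pl$level != "Th12"] == 1))
  expect_equal(rep$recall, 8 / 9)
  expect_equal(rep$precision, 1)
  expect_equal(rep$image_success_rate, 0)
})

test_that("pooled tallies reproduce the arithmetic oracle", {
  # 10 single-truth images engineered to pool 7 TP, 1 FP, 3 FN
  mk_img <- function(hit, extra_fp = FALSE) {
    truth <- bounding_boxes(0, 0, 10, 10)
    pred <- if (hit) truth else bounding_boxes(50, 50, 60, 60)
    if (extra_fp) {
      pred <- rbind(pred, bounding_boxes(100, 100, 110, 110))
      class(pred) <- c("bounding_boxes", "data.frame")
    }
    list(pred = pred, truth = truth)
  }
  dataset <- c(lapply(1:7, function(i) mk_img(TRUE)),
               lapply(1:3, function(i) mk_img(FALSE)))
  # the 3 misses each contribute 1 FP (stray box) + 1 FN; trim the
  # stray boxes from two images so the pooled FP count is exactly 1
  for (i in 8:9) dataset[[i]]$pred <- dataset[[i]]$pred[0, ]
  rep <- evaluate_detections(dataset)
  expect_equal(c(rep$tp, rep$fp, rep$fn), c(7, 1, 3))
  expect_equal(rep$precision, 7 / 8)
  expect_equal(rep$recall, 7 / 10)
  expect_equal(rep$f1, 2 * (7 / 8) * (7 / 10) / (7 / 8 + 7 / 10))
})

test_that("shrinking predicted boxes weakly decreases mean IoU", {
  dataset <- lapply(1:5, perfect_phantom_pair)
  shrink <- function(b, f) {
    cx <- (b$x_min + b$x_max) / 2; cy <- (b$y_min + b$y_max) / 2
    w <- (b$x_max - b$x_min) * f / 2; h <- (b$y_max - b$y_min) * f / 2
    bounding_boxes(cx - w, cy - h, cx + w, cy + h, level = b$level,
                   confidence = b$confidence)
  }
  fs <- c(1, 0.9, 0.8, 0.72)
  mious <- vapply(fs, function(f) {
    ds <- lapply(dataset, function(p) list(pred = shrink(p$pred, f),
                                           truth = p$truth))
    evaluate_detections(ds)$mean_iou
  }, numeric(1))
  expect_true(all(diff(mious) < 1e-12))
  expect_error(evaluate_detections(list()), class = "empty_dataset_error")
})
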