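# Agreement statistics and threshold diagnostics.
#
# Frozen reference values for the 4-pair fixture were computed with
# independent oracles (hand arithmetic; scipy/pingouin for r, CCC,
# ICC(A,1) and its F-based confidence bounds).

four_pairs <- data.frame(automated_deg = c(30, 40, 50, 60),
                         manual_deg = c(31, 42, 49, 58))

test_that("perfect agreement saturates every statistic", {
  p <- data.frame(automated_deg = c(30, 40, 50, 60, 35),
                  manual_deg = c(30, 40, 50, 60, 35))
  a <- agreement_stats(p)
  expect_equal(a$pearson_r, 1)
  expect_equal(a$icc_a1, 1)
  expect_equal(a$ccc, 1)
  expect_equal(a$rmse_deg, 0)
  expect_equal(a$mae_deg, 0)
  expect_equal(c(a$ba_loa_low_deg, a$ba_loa_high_deg), c(0, 0))
})

test_that("a pure offset separates consistency from agreement", {
  p <- data.frame(automated_deg = c(30, 40, 50, 60))
  p$manual_deg <- p$automated_deg + 3
  a <- agreement_stats(p)
  expect_equal(a$pearson_r, 1)
  expect_lt(a$ccc, 1)
  expect_lt(a$icc_a1, 1)
  expect_equal(a$ba_mean_diff_deg, -3)
  expect_equal(c(a$ba_loa_low_deg, a$ba_loa_high_deg), c(-3, -3))
})

test_that("the 4-pair fixture reproduces the frozen oracle values", {
  a <- agreement_stats(four_pairs)
  expect_equal(a$rmse_deg, sqrt(2.5), tolerance = 1e-12)
  expect_equal(a$mse_deg2, 2.5, tolerance = 1e-12)
  expect_equal(a$mae_deg, 1.5, tolerance = 1e-12)
  # differences (-1, -2, +1, +2) sum to zero
  expect_equal(a$ba_mean_diff_deg, 0, tolerance = 1e-12)
  expect_equal(a$ba_loa_high_deg, 1.96 * sqrt(10 / 3), tolerance = 1e-12)
  expect_equal(a$ba_loa_low_deg, -1.96 * sqrt(10 / 3), tolerance = 1e-12)
  expect_equal(a$median_ae_deg, 1.5, tolerance = 1e-12)
  expect_equal(a$p95_ae_deg, 2.0, tolerance = 1e-12)
  expect_equal(a$pearson_r, 0.9964037900472442, tolerance = 1e-12)
  expect_equal(a$ccc, 0.9887640449438202, tolerance = 1e-12)
  expect_equal(a$icc_a1, 0.9915492957746477, tolerance = 1e-12)
  expect_equal(a$icc_ci, c(0.8746274100164141, 0.9994511998252013),
               tolerance = 1e-9)
})

test_that("degenerate inputs raise classed statistical errors", {
  expect_error(agreement_stats(four_pairs[1:2, ]),
               class = "too_few_pairs_error")
  const <- data.frame(automated_deg = rep(45, 5), manual_deg = 41:45)
  expect_error(agreement_stats(const), class = "zero_variance_error")
})

test_that("rmse >= mae with equality iff all |d| are equal; column swap mirrors LoA", {
  set.seed(8)
  for (i in 1:30) {
    p <- data.frame(automated_deg = stats::runif(12, 20, 70))
    p$manual_deg <- p$automated_deg + stats::rnorm(12, 0, 2)
    a <- agreement_stats(p)
    expect_gte(a$rmse_deg, a$mae_deg)
    sw <- agreement_stats(data.frame(automated_deg = p$manual_deg,
                                     manual_deg = p$automated_deg))
    expect_equal(sw$ba_mean_diff_deg, -a$ba_mean_diff_deg)
    expect_equal(sw$ba_loa_low_deg, -a$ba_loa_high_deg)
    expect_equal(sw$ba_loa_high_deg, -a$ba_loa_low_deg)
  }
  # constant |d| = 2 with mixed signs: rmse == mae
  p2 <- data.frame(automated_deg = c(30, 40, 50, 60),
                   manual_deg = c(32, 38, 52, 58))
  a2 <- agreement_stats(p2)
  expect_equal(a2$rmse_deg, a2$mae_deg)
})

test_that("adding an offset lowers ICC and CCC but not r", {
  set.seed(9)
  for (i in 1:20) {
    base <- stats::runif(15, 25, 65)
    p <- data.frame(automated_deg = base,
                    manual_deg = base + stats::rnorm(15, 0, 1))
    a0 <- agreement_stats(p)
    p$manual_deg <- p$manual_deg + 5
    a1 <- agreement_stats(p)
    expect_equal(a1$pearson_r, a0$pearson_r, tolerance = 1e-12)
    expect_lt(a1$ccc, a0$ccc)
    expect_lt(a1$icc_a1, a0$icc_a1)
  }
})

test_that("Wilson intervals contain the point estimate and stay in [0,1]", {
  set.seed(10)
  for (i in 1:50) {
    n <- sample(1:200, 1)
    k <- sample(0:n, 1)
    ci <- wilson_ci(k, n)
    expect_gte(ci[1], 0); expect_lte(ci[2], 1)
    expect_gte(k / n, ci[1]); expect_lte(k / n, ci[2])
  }
})

test_that("ROC AUC handles perfect, constant and hand-computed scorers", {
  # perfect classifier
  p <- data.frame(automated_deg = c(45, 50, 30, 35),
                  manual_deg = c(45, 50, 30, 35))
  d <- diagnostics_at_threshold(p)
  expect_equal(d$sensitivity, 1)
  expect_equal(d$specificity, 1)
  expect_equal(d$auc, 1)
  # constant score: single ROC step, trapezoid gives 1/2
  expect_equal(roc_auc(rep(3, 10), rep(c(TRUE, FALSE), 5)), 0.5)
  # hand-computed: scores 1..4, labels F F T T; AUC = 1
  expect_equal(roc_auc(1:4, c(FALSE, FALSE, TRUE, TRUE)), 1)
  # one inverted pair among the four pos/neg comparisons -> AUC = 3/4
  expect_equal(roc_auc(1:4, c(FALSE, TRUE, FALSE, TRUE)), 0.75)
})

test_that("printed confusion-matrix counts reproduce the published table", {
  d <- confusion_from_counts(63, 11, 5, 101)
  expect_equal(d$n, 180)
  expect_equal(round(100 * d$ppv), 85)
  expect_equal(round(100 * d$prevalence), 38)
  expect_equal(d$sensitivity, 63 / 68)
  # counts imply 90% specificity and 95% NPV (the published prose rounds
  # these differently; the counts are authoritative here)
  expect_equal(round(100 * d$specificity), 90)
  expect_equal(round(100 * d$npv), 95)
  # frozen Wilson bounds for sensitivity 63/68
  expect_equal(d$sensitivity_ci, c(0.839148, 0.968185), tolerance = 1e-5)

  d2 <- confusion_from_counts(1, 0, 0, 1)
  expect_equal(c(d2$sensitivity, d2$specificity, d2$ppv, d2$npv),
               rep(1, 4))
  d3 <- confusion_from_counts(0, 0, 5, 5)
  expect_equal(d3$sensitivity, 0)
  expect_true(is.na(d3$ppv))
  expect_error(confusion_from_counts(-1, 0, 0, 1), class = "parse_error")
})

test_that("cohort-level agreement converges toward the injected noise model", {
  # with observer noise only (no centroid noise), the automated angle is
  # exact, so RMSE vs manual equals the manual-error SD ~ sd/sqrt(2)
  co <- make_cohort(400, spec_template = phantom_spec(centroid_noise_sd = 0),
                    obs_a = observer_model(0, 1.5, 1),
                    obs_b = observer_model(0, 1.5, 2), seed = 17)
  a <- agreement_stats(data.frame(automated_deg = co$automated_deg,
                                  manual_deg = co$manual_deg))
  # consensus redraws make the exact SD smaller than 1.5/sqrt(2); bracket it
  expect_lt(a$rmse_deg, 1.5 / sqrt(2) * 1.15)
  expect_gt(a$rmse_deg, 1.5 / sqrt(2) * 0.55)
  expect_lt(abs(a$ba_mean_diff_deg), 3 * a$rmse_deg / sqrt(400))
  expect_gt(a$pearson_r, 0.97)
})
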