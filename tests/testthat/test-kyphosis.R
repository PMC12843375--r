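# Kyphosis measurement pipeline: QC gating, exactness, invariances.

test_that("noiseless arcs are recovered exactly and QC passes", {
  vc <- arc_centroids(46.1, cx = 320, cy = 320, r = 300, phi0_deg = 112)
  m <- measure_kyphosis(vc)
  expect_equal(m$qc_flag, "ok")
  expect_equal(m$central_angle_deg, 46.1, tolerance = 1e-6 / 46.1)
  expect_equal(m$cobb_equiv_deg, m$central_angle_deg, tolerance = 1e-9)
  expect_identical(m$levels_used, thoracic_levels())

  # nearly-straight spine: theta = 0.5 deg still yields a finite fit,
  # cross-checked against the chord-formula oracle
  vc2 <- arc_centroids(0.5, r = 1000, phi0_deg = 80)
  m2 <- measure_kyphosis(vc2)
  expect_equal(m2$qc_flag, "ok")
  expect_equal(m2$central_angle_deg, 0.5, tolerance = 1e-3)
  chord <- sqrt((vc2$x[9] - vc2$x[1])^2 + (vc2$y[9] - vc2$y[1])^2)
  theta_chord <- 2 * asin(chord / (2 * m2$circle$radius)) * 180 / pi
  expect_equal(m2$central_angle_deg, theta_chord, tolerance = 1e-6)
})

test_that("incomplete or degenerate centroid sets are QC-flagged, not errors", {
  lv <- thoracic_levels()
  p <- arc_points(46.1, r = 300)
  no12 <- vertebral_centroids(lv[1:8], p[1:8, 1], p[1:8, 2])
  m <- measure_kyphosis(no12)
  expect_equal(m$qc_flag, "unsuitable")
  expect_match(m$qc_reason, "Th12")
  expect_true(is.na(m$central_angle_deg))
  expect_true(is.na(m$cobb_equiv_deg))

  collinear <- vertebral_centroids(lv, seq(0, 8), 2 * seq(0, 8))
  mc <- measure_kyphosis(collinear)
  expect_equal(mc$qc_flag, "unsuitable")
  expect_match(mc$qc_reason, "collinear")

  # chain zig-zagging across the chord is geometry-inconsistent:
  # reflect Th8 across the Th4-Th12 chord
  zig <- arc_points(46.1, r = 300)
  u <- zig[9, ] - zig[1, ]; u <- u / sqrt(sum(u^2))
  w <- zig[5, ] - zig[1, ]
  zig[5, ] <- zig[1, ] + 2 * sum(w * u) * u - w
  mz <- measure_kyphosis(vertebral_centroids(lv, zig[, 1], zig[, 2]))
  expect_equal(mz$qc_flag, "unsuitable")
  expect_match(mz$qc_reason, "geometry-inconsistent")
})

test_that("exact-fit recovery holds across the physiological angle range", {
  set.seed(11)
  for (i in 1:50) {
    theta <- stats::runif(1, 1.5, 120)
    rc <- random_circle()
    vc <- arc_centroids(theta, cx = rc$cx, cy = rc$cy, r = rc$r,
                        phi0_deg = stats::runif(1, 0, 360))
    m <- measure_kyphosis(vc)
    expect_equal(m$qc_flag, "ok")
    expect_lt(abs(m$central_angle_deg - theta), 1e-6)
  }
})

test_that("the angle is invariant to translation, rotation and scaling", {
  vc <- arc_centroids(52.3, cx = 5, cy = -3, r = 40, phi0_deg = 200)
  base <- measure_kyphosis(vc)$central_angle_deg
  p <- cbind(vc$x, vc$y)
  set.seed(3)
  for (i in 1:20) {
    ang <- stats::runif(1, 0, 2 * pi)
    R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
    s <- stats::runif(1, 0.1, 10)
    q <- s * p %*% R + matrix(stats::runif(2, -100, 100), 9, 2, byrow = TRUE)
    m <- measure_kyphosis(vertebral_centroids(thoracic_levels(), q[, 1], q[, 2]))
    expect_equal(m$central_angle_deg, base, tolerance = 1e-9)
  }
})

test_that("for a fixed chord, a smaller fitted radius gives a larger theta", {
  chord <- 100
  radii <- seq(60, 500, length.out = 20)
  thetas <- vapply(radii, function(r) {
    circ <- structure(list(center = c(x = 0, y = 0), radius = r),
                      class = "fitted_circle")
    half <- asin(chord / (2 * r))
    p1 <- c(r * cos(pi / 2 - half), r * sin(pi / 2 - half))
    p2 <- c(r * cos(pi / 2 + half), r * sin(pi / 2 + half))
    central_angle(circ, p1, p2)
  }, numeric(1))
  expect_true(all(diff(thetas) < 0))  # radius up => theta down
})

test_that("classification applies the inclusive 40-degree rule", {
  expect_equal(classify_kyphosis(45.3), "significant")
  expect_equal(classify_kyphosis(35.2), "not_significant")
  expect_equal(classify_kyphosis(40.0), "significant")
  expect_equal(classify_kyphosis(c(39.999, NA)), c("not_significant", NA))
  expect_equal(classify_kyphosis(30, threshold_deg = 25), "significant")
})

test_that("measurement reports serialise to JSON with the circle block", {
  vc <- arc_centroids(46.1, cx = 320, cy = 320, r = 300, phi0_deg = 112,
                      scan_id = "s1")
  m <- measure_kyphosis(vc)
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_measurement_report(m, path)
  got <- jsonlite::read_json(path, simplifyVector = FALSE)[[1]]
  expect_equal(got$scan_id, "s1")
  expect_equal(got$qc_flag, "ok")
  expect_equal(got$central_angle_deg, m$central_angle_deg)
  expect_equal(got$circle$r, m$circle$radius)
})
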