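# Shared fixture builders: arcs, random circles, and an independent
# brute-force circle-fit oracle (coarse-to-fine grid search over the
# centre with the radius profiled out as the mean centre distance).

# n points at equal angular steps spanning theta_deg, starting at
# phi0_deg, on the circle (cx, cy, r).
arc_points <- function(theta_deg, n = 9, cx = 0, cy = 0, r = 1, phi0_deg = 90) {
  phi <- (phi0_deg + theta_deg * seq(0, n - 1) / (n - 1)) * pi / 180
  cbind(x = cx + r * cos(phi), y = cy + r * sin(phi))
}

arc_centroids <- function(theta_deg, n = 9, cx = 0, cy = 0, r = 1,
                          phi0_deg = 90, scan_id = "arc") {
  p <- arc_points(theta_deg, n, cx, cy, r, phi0_deg)
  vertebral_centroids(thoracic_levels()[seq_len(n)], p[, 1], p[, 2],
                      scan_id = scan_id)
}

random_circle <- function() {
  list(cx = stats::runif(1, -50, 50), cy = stats::runif(1, -50, 50),
       r = stats::runif(1, 0.5, 100))
}

# Independent oracle: minimize sum((|p - c| - mean|p - c|)^2) by nested
# grid refinement; never calls fit_circle.
grid_fit_circle <- function(points, center0, half_width, grid_n = 13) {
  obj <- function(cx, cy) {
    d <- sqrt((points[, 1] - cx)^2 + (points[, 2] - cy)^2)
    sum((d - mean(d))^2)
  }
  best <- center0
  hw <- half_width
  # the radial-residual objective has a long, gently curved valley on
  # short arcs: track the argmin by re-centring, expanding the window
  # whenever the winner sits on its edge and shrinking only when interior
  iter <- 0
  while (hw > 1e-9 && (iter <- iter + 1) < 3000) {
    gx <- seq(best[1] - hw, best[1] + hw, length.out = grid_n)
    gy <- seq(best[2] - hw, best[2] + hw, length.out = grid_n)
    vals <- outer(gx, gy, Vectorize(obj))
    idx <- arrayInd(which.min(vals), dim(vals))
    interior <- all(idx > 1 & idx < grid_n)
    best <- c(gx[idx[1]], gy[idx[2]])
    hw <- if (interior) hw * 0.45 else hw * 2
  }
  d <- sqrt((points[, 1] - best[1])^2 + (points[, 2] - best[2])^2)
  list(center = best, radius = mean(d))
}

# Circumcentre of three points (closed-form perpendicular-bisector
# intersection); independent starting point for the grid oracle.
circumcenter3 <- function(p1, p2, p3) {
  ax <- p1[1]; ay <- p1[2]; bx <- p2[1]; by <- p2[2]; cx <- p3[1]; cy <- p3[2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
  c(ux, uy)
}

perfect_phantom_pair <- function(seed) {
  sp <- phantom_spec(true_central_angle_deg = 40 + (seed %% 20),
                     centroid_noise_sd = 0, background_noise_sd = 0,
                     blur_sigma = 0, seed = seed)
  truth <- make_centroids(sp)$truth
  tb <- bounding_boxes(truth$true_boxes$x_min, truth$true_boxes$y_min,
                       truth$true_boxes$x_max, truth$true_boxes$y_max,
                       level = truth$true_boxes$level)
  list(pred = tb, truth = tb)
}
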