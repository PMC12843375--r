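# Least-squares circle geometry.
#
# The global thoracic curve is summarised by the best-fit circle through
# the vertebral centroid chain. The algebraic (Kasa) fit linearises
# x^2 + y^2 = 2*cx*x + 2*cy*y + t and solves in closed form; the geometric
# fit refines (cx, cy) by minimising the sum of squared radial residuals
# sum_i (|p_i - c| - r)^2, seeded by the algebraic solution, with the
# radius profiled out as the mean centre distance.

as_points <- function(points) {
  if (is.data.frame(points)) {
    m <- cbind(points$x, points$y)
  } else {
    m <- as.matrix(points)
  }
  if (is.null(dim(m)) || ncol(m) != 2) {
    abort("points must be an n x 2 matrix or data frame with x, y", "point_error")
  }
  storage.mode(m) <- "double"
  if (!all(is.finite(m))) abort("non-finite point coordinates", "point_error")
  unname(m)
}

# Scale-free collinearity test: ratio of singular values of the centred
# coordinate matrix.
collinearity_ratio <- function(m) {
  ctr <- sweep(m, 2, colMeans(m))
  d <- svd(ctr, nu = 0, nv = 0)$d
  if (d[1] == 0) 0 else d[2] / d[1]
}

#' Fit a circle to 2-D points by least squares
#'
#' @param points An `n x 2` matrix or a data frame with columns `x`, `y`
#'   (`n >= 3`).
#' @param method `"algebraic"` for the closed-form Kasa fit,
#'   `"geometric"` to additionally refine centre and radius by iterative
#'   minimisation of the summed squared radial residuals (Nelder-Mead/BFGS
#'   via [stats::optim()], seeded by the algebraic solution).
#' @param collinearity_tol Relative singular-value ratio below which the
#'   points are declared collinear (circle degenerate, radius unbounded).
#' @return An object of class `fitted_circle`: list with `center` (x, y),
#'   `radius`, `rms_residual` (RMS of `| |p - center| - radius |`) and
#'   `n_points`.
#' @export
#' @examples
#' fit_circle(rbind(c(1, 0), c(0, 1), c(-1, 0)))
fit_circle <- function(points, method = c("algebraic", "geometric"),
                       collinearity_tol = 1e-10) {
  method <- match.arg(method)
  m <- as_points(points)
  n <- nrow(m)
  if (n < 3) {
    abort(sprintf("circle fit needs at least 3 points, got %d", n),
          "insufficient_points_error")
  }
  if (collinearity_ratio(m) < collinearity_tol) {
    abort("points are collinear within tolerance; circle fit is degenerate",
          "collinear_points_error")
  }
  x <- m[, 1]; y <- m[, 2]
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  sol <- qr.solve(A, b)
  center <- sol[1:2]
  radius <- sqrt(sol[3] + sum(center^2))

  if (method == "geometric") {
    # damped Gauss-Newton on residuals e_i = |p_i - c| - r, Kasa-seeded;
    # converges to machine precision even on ill-conditioned short arcs
    par <- c(center, radius)
    sse <- function(p) {
      di <- sqrt((x - p[1])^2 + (y - p[2])^2)
      sum((di - p[3])^2)
    }
    f_old <- sse(par)
    for (it in seq_len(200)) {
      di <- sqrt((x - par[1])^2 + (y - par[2])^2)
      J <- cbind(-(x - par[1]) / di, -(y - par[2]) / di, -1)
      e <- di - par[3]
      step <- tryCatch(qr.solve(J, e), error = function(err) NULL)
      if (is.null(step)) break
      lambda <- 1
      repeat {
        cand <- par - lambda * step
        if (sse(cand) <= f_old || lambda < 1e-8) break
        lambda <- lambda / 2
      }
      moved <- sqrt(sum((lambda * step)^2))
      par <- par - lambda * step
      f_new <- sse(par)
      if (moved < 1e-13 * (abs(par[3]) + 1) || f_old - f_new < 1e-15 * (f_old + 1e-300)) {
        f_old <- f_new
        break
      }
      f_old <- f_new
    }
    center <- par[1:2]
    radius <- mean(sqrt((x - center[1])^2 + (y - center[2])^2))
  }

  di <- sqrt((x - center[1])^2 + (y - center[2])^2)
  structure(list(center = c(x = unname(center[1]), y = unname(center[2])),
                 radius = unname(radius),
                 rms_residual = sqrt(mean((di - radius)^2)),
                 n_points = n),
            class = "fitted_circle")
}

#' @export
print.fitted_circle <- function(x, ...) {
  cat(sprintf("Fitted circle: center (%.4g, %.4g), radius %.4g, RMS residual %.3g (%d points)\n",
              x$center[1], x$center[2], x$radius, x$rms_residual, x$n_points))
  invisible(x)
}

unit_radials <- function(circle, p_start, p_end) {
  c0 <- circle$center
  v1 <- c(p_start[1] - c0[1], p_start[2] - c0[2])
  v2 <- c(p_end[1] - c0[1], p_end[2] - c0[2])
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  eps <- 1e-12 * circle$radius
  if (n1 <= eps || n2 <= eps) {
    abort("endpoint coincides with the circle center; angle undefined",
          "degenerate_angle_error")
  }
  list(u1 = v1 / n1, u2 = v2 / n2)
}

angle_between_deg <- function(u1, u2) {
  cross <- u1[1] * u2[2] - u1[2] * u2[1]
  dot <- sum(u1 * u2)
  as.numeric(rad2deg(atan2(abs(cross), dot)))
}

#' Central angle subtended by two points
#'
#' Angle at the fitted circle's centre between the radii towards
#' `p_start` and `p_end`, in degrees on the minor arc `[0, 180]`. For the
#' kyphosis measurement the endpoints are the Th4 and Th12 centroids.
#'
#' @param circle A [fit_circle()] result.
#' @param p_start,p_end Length-2 numeric points.
#' @return Angle in degrees in `[0, 180]`.
#' @export
central_angle <- function(circle, p_start, p_end) {
  u <- unit_radials(circle, p_start, p_end)
  angle_between_deg(u$u1, u$u2)
}

#' Cobb-equivalent angle from tangent lines
#'
#' Projects the endpoints radially onto the fitted circle, constructs the
#' tangent to the circle at each projection (perpendicular to the radius,
#' oriented consistently with the arc traversal) and returns the angle
#' between the tangents in degrees, `[0, 180]`. For endpoints exactly on
#' one circle this equals the central angle (tangent-chord identity); the
#' antipodal limit is reported as 180.
#'
#' @inheritParams central_angle
#' @return Angle in degrees in `[0, 180]`.
#' @export
cobb_from_tangents <- function(circle, p_start, p_end) {
  u <- unit_radials(circle, p_start, p_end)
  # tangent direction: radial unit rotated +90 degrees (same sense at both
  # endpoints, so the tangent-tangent angle equals the radius-radius angle)
  t1 <- c(-u$u1[2], u$u1[1])
  t2 <- c(-u$u2[2], u$u2[1])
  angle_between_deg(t1, t2)
}
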