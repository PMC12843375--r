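# Synthetic spine phantoms.
#
# The clinical DEXA images behind the method are not publicly available,
# so every downstream stage is exercised on synthetic spines with known
# ground truth: nine centroids placed at equal angular steps on a circular
# arc of chosen curvature, perturbed by detector-like Gaussian noise and
# per-level dropout, optionally rendered as a DEXA-like raster phantom.
# All randomness is governed by the spec's seed.

#' Phantom specification
#'
#' Generative parameters for one synthetic spine. Defaults emulate a
#' 640 x 640 lateral acquisition (intensities normalised to `[0, 1]`)
#' with a hyperkyphotic arc typical of advanced axial spondyloarthritis.
#'
#' @param true_central_angle_deg True arc central angle theta* in degrees,
#'   in (0, 180).
#' @param radius Arc radius in pixels.
#' @param centroid_noise_sd SD (px) of i.i.d. Gaussian noise added to each
#'   observed centroid coordinate.
#' @param dropout_prob Per-level probability of a missed detection; scalar
#'   or length-9 vector ordered Th4..Th12.
#' @param image_size Integer `(width, height)` in pixels.
#' @param vertebra_size Numeric `(body width, body height)` in pixels;
#'   height is the extent along the arc tangent (craniocaudal), width the
#'   anteroposterior extent.
#' @param background_noise_sd SD of additive Gaussian intensity noise.
#' @param blur_sigma Gaussian blur SD in pixels.
#' @param seed Integer seed fixing all randomness for this phantom.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(true_central_angle_deg = 45.3,
                         radius = 300,
                         centroid_noise_sd = 1,
                         dropout_prob = 0,
                         image_size = c(640, 640),
                         vertebra_size = c(38, 24),
                         background_noise_sd = 0.05,
                         blur_sigma = 1,
                         seed = 1L) {
  if (!is_scalar_number(true_central_angle_deg) ||
      true_central_angle_deg <= 0 || true_central_angle_deg >= 180) {
    abort("true_central_angle_deg must lie in (0, 180)", "spec_error")
  }
  if (!is_scalar_number(radius) || radius <= 0) {
    abort("radius must be positive", "spec_error")
  }
  dropout_prob <- rep_len(dropout_prob, 9L)
  if (any(dropout_prob < 0 | dropout_prob > 1)) {
    abort("dropout_prob must lie in [0, 1]", "spec_error")
  }
  if (centroid_noise_sd < 0 || background_noise_sd < 0 || blur_sigma < 0) {
    abort("noise parameters must be nonnegative", "spec_error")
  }
  structure(list(true_central_angle_deg = true_central_angle_deg,
                 radius = radius,
                 n_levels = 9L,
                 start_level = "Th4",
                 centroid_noise_sd = centroid_noise_sd,
                 dropout_prob = dropout_prob,
                 image_size = as.integer(image_size),
                 vertebra_size = as.numeric(vertebra_size),
                 background_noise_sd = background_noise_sd,
                 blur_sigma = blur_sigma,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# True arc geometry shared by the generator and the renderer. Anterior
# convexity is fixed leftward: the arc bulges toward small x, with Th4 at
# the top of the image (small y).
phantom_arc <- function(spec) {
  theta <- deg2rad(spec$true_central_angle_deg)
  w <- spec$image_size[1]; h <- spec$image_size[2]
  cx <- w / 2 + spec$radius
  cy <- h / 2
  phi <- pi - theta * (seq(0, spec$n_levels - 1) / (spec$n_levels - 1) - 0.5)
  list(center = c(cx, cy),
       phi = phi,
       x = cx + spec$radius * cos(phi),
       y = cy + spec$radius * sin(phi))
}

#' Generate the centroid chain of a synthetic spine
#'
#' Places nine true centroids at equal angular steps spanning exactly the
#' spec's central angle on a circle of the given radius, arc midpoint at
#' the image centre and convex toward image left. Observed centroids add
#' i.i.d. Gaussian noise; each level is independently dropped with its
#' dropout probability. Deterministic given the spec seed.
#'
#' @param spec A [phantom_spec()].
#' @param scan_id Scan identifier for the generated set.
#' @return List with `centroids` (the observed, possibly incomplete
#'   [vertebral_centroids()]) and `truth` (list: `true_angle_deg`,
#'   `true_centroids`, `true_boxes` data frame of axis-aligned hulls of
#'   the rendered vertebral bodies).
#' @export
make_centroids <- function(spec, scan_id = "phantom") {
  stopifnot(inherits(spec, "phantom_spec"))
  arc <- phantom_arc(spec)
  wv <- spec$vertebra_size[1]; hv <- spec$vertebra_size[2]
  margin <- sqrt(wv^2 + hv^2) / 2
  w <- spec$image_size[1]; h <- spec$image_size[2]
  if (any(arc$x < margin) || any(arc$x > w - margin) ||
      any(arc$y < margin) || any(arc$y > h - margin)) {
    abort("arc does not fit the image bounds at this radius/angle", "spec_error")
  }

  levels <- thoracic_levels()
  true_vc <- vertebral_centroids(levels, arc$x, arc$y, 1,
                                 scan_id = paste0(scan_id, "_truth"))

  boxes <- do.call(rbind, lapply(seq_along(levels), function(i) {
    u <- c(cos(arc$phi[i]), sin(arc$phi[i]))      # radial unit
    tv <- c(-u[2], u[1])                          # tangent unit
    corners <- t(sapply(list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)),
                        function(s) {
                          c(arc$x[i], arc$y[i]) +
                            s[1] * (hv / 2) * tv + s[2] * (wv / 2) * u
                        }))
    data.frame(level = levels[i],
               x_min = min(corners[, 1]), y_min = min(corners[, 2]),
               x_max = max(corners[, 1]), y_max = max(corners[, 2]),
               stringsAsFactors = FALSE)
  }))

  obs <- with_seed(spec$seed, {
    noise <- matrix(stats::rnorm(18, 0, spec$centroid_noise_sd), ncol = 2)
    keep <- stats::runif(9) >= spec$dropout_prob
    list(x = arc$x + noise[, 1], y = arc$y + noise[, 2], keep = keep)
  })
  observed <- vertebral_centroids(levels[obs$keep],
                                  obs$x[obs$keep], obs$y[obs$keep],
                                  confidence = 1, scan_id = scan_id)
  list(centroids = observed,
       truth = list(true_angle_deg = spec$true_central_angle_deg,
                    true_centroids = true_vc,
                    true_boxes = boxes))
}

#' Manual-observer model
#'
#' A physician reading the Cobb angle from the image is modelled as the
#' true angle plus a systematic bias plus zero-mean Gaussian noise.
#'
#' @param bias_deg Systematic bias in degrees.
#' @param noise_sd_deg Reading noise SD in degrees (>= 0).
#' @param seed Integer seed for this observer.
#' @return A list of class `observer_model`.
#' @export
observer_model <- function(bias_deg = 0, noise_sd_deg = 1.5, seed = 1L) {
  if (noise_sd_deg < 0) abort("noise_sd_deg must be >= 0", "spec_error")
  structure(list(bias_deg = bias_deg, noise_sd_deg = noise_sd_deg,
                 seed = as.integer(seed)),
            class = "observer_model")
}

#' Simulate the two-observer manual Cobb measurement with consensus
#'
#' Two independent observers each read the angle; if the readings differ
#' by at most the consensus threshold (2 degrees by default) their mean is
#' returned. Larger discrepancies trigger a consensus discussion, modelled
#' as both observers re-reading with halved noise SD and the mean of the
#' re-readings being adopted. Deterministic given the seed.
#'
#' @param true_angle_deg True angle in degrees.
#' @param obs_a,obs_b [observer_model()] objects.
#' @param consensus_threshold_deg Maximum tolerated inter-observer
#'   difference in degrees.
#' @param seed Integer seed; defaults to a combination of the two
#'   observer seeds.
#' @return The simulated manual angle in degrees.
#' @export
simulate_manual_cobb <- function(true_angle_deg, obs_a, obs_b,
                                 consensus_threshold_deg = 2,
                                 seed = NULL) {
  stopifnot(inherits(obs_a, "observer_model"), inherits(obs_b, "observer_model"),
            is_scalar_number(true_angle_deg))
  if (is.null(seed)) seed <- child_seed(obs_a$seed, obs_b$seed)
  with_seed(seed, {
    ra <- true_angle_deg + obs_a$bias_deg + stats::rnorm(1, 0, obs_a$noise_sd_deg)
    rb <- true_angle_deg + obs_b$bias_deg + stats::rnorm(1, 0, obs_b$noise_sd_deg)
    if (abs(ra - rb) <= consensus_threshold_deg) {
      (ra + rb) / 2
    } else {
      ra2 <- true_angle_deg + obs_a$bias_deg +
        stats::rnorm(1, 0, obs_a$noise_sd_deg / 2)
      rb2 <- true_angle_deg + obs_b$bias_deg +
        stats::rnorm(1, 0, obs_b$noise_sd_deg / 2)
      (ra2 + rb2) / 2
    }
  })
}

#' Simulate a paired cohort of scans
#'
#' Draws per-scan true angles from a truncated normal (bounds 5-120
#' degrees, covering the physiological-to-severe range), generates a
#' centroid phantom per scan, measures it automatically and simulates the
#' two-observer manual reading. QC-flagged scans carry `NA` automated
#' angles, mirroring referral to manual measurement.
#'
#' @param n Number of scans (>= 2).
#' @param angle_mean,angle_sd Mean and SD in degrees of the true-angle
#'   distribution (cohort defaults: 45.3 +/- 7.8 for the inflammatory
#'   high-curvature group, 35.2 +/- 6.5 for controls).
#' @param spec_template A [phantom_spec()]; its angle and seed are
#'   replaced per scan.
#' @param obs_a,obs_b [observer_model()] objects.
#' @param seed Master seed.
#' @param config A [measurement_config()].
#' @return Data frame with columns `scan_id`, `true_deg`, `automated_deg`,
#'   `manual_deg`, `qc_flag`.
#' @export
make_cohort <- function(n, angle_mean = 45.3, angle_sd = 7.8,
                        spec_template = phantom_spec(),
                        obs_a = observer_model(seed = 11L),
                        obs_b = observer_model(seed = 12L),
                        seed = 1L,
                        config = measurement_config()) {
  if (!is_scalar_number(n) || n < 2) abort("cohort needs n >= 2", "spec_error")
  n <- as.integer(n)
  draws <- with_seed(seed, {
    list(theta = rtruncnorm(n, angle_mean, angle_sd, 5, 120),
         scan_seed = sample.int(2147483600L, n))
  })
  rows <- lapply(seq_len(n), function(i) {
    sp <- spec_template
    sp$true_central_angle_deg <- draws$theta[i]
    sp$seed <- draws$scan_seed[i]
    mk <- make_centroids(sp, scan_id = sprintf("scan%04d", i))
    meas <- measure_kyphosis(mk$centroids, config)
    manual <- simulate_manual_cobb(draws$theta[i], obs_a, obs_b,
                                   seed = child_seed(draws$scan_seed[i], 1L))
    data.frame(scan_id = sprintf("scan%04d", i),
               true_deg = draws$theta[i],
               automated_deg = if (meas$qc_flag == "ok") meas$central_angle_deg else NA_real_,
               manual_deg = manual,
               qc_flag = meas$qc_flag,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
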