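# Raster phantom rendering and plain-text image I/O.
#
# Images are numeric matrices (rows = y, columns = x) with intensities in
# [0, 1], emulating a normalised lateral DEXA acquisition: bright
# vertebral bodies on a dark background. File round-trips use plain-text
# PGM (P2), the only raster format the package reads or writes.

# Separable Gaussian blur with edge replication.
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  conv1 <- function(v) {
    padded <- c(rep(v[1], r), v, rep(v[length(v)], r))
    stats::filter(padded, k, sides = 2)[(r + 1):(r + length(v))]
  }
  img <- apply(img, 2, conv1)
  t(apply(img, 1, conv1))
}

#' Render a raster phantom from ground truth
#'
#' Draws each vertebral body as a bright filled rectangle (long axis
#' tangent to the arc) at its true centroid, applies Gaussian blur then
#' additive Gaussian intensity noise, and clips to `[0, 1]`. Ground-truth
#' boxes (axis-aligned hulls of the rotated rectangles) accompany the
#' image together with their YOLO-format annotation lines.
#'
#' @param spec A [phantom_spec()].
#' @param truth The `truth` element returned by [make_centroids()].
#' @param body_intensity Intensity of the rendered bodies before blur.
#' @return List with `image` (height x width matrix in `[0, 1]`), `boxes`
#'   (data frame `level`, `x_min`, `y_min`, `x_max`, `y_max`) and
#'   `annotation` (character vector of YOLO lines).
#' @export
render_phantom <- function(spec, truth, body_intensity = 0.9) {
  stopifnot(inherits(spec, "phantom_spec"))
  w <- spec$image_size[1]; h <- spec$image_size[2]
  img <- matrix(0, nrow = h, ncol = w)
  tc <- truth$true_centroids
  wv <- spec$vertebra_size[1]; hv <- spec$vertebra_size[2]

  if (nrow(tc) > 1) {
    d <- sqrt(diff(tc$x)^2 + diff(tc$y)^2)
    if (any(d < hv)) {
      abort("vertebral bodies overlap: arc spacing below body height",
            "spec_error")
    }
  }

  if (nrow(tc)) {
    arc <- phantom_arc(spec)
    idx <- match(tc$level, thoracic_levels())
    # pixel centres in 0-based continuous coordinates
    for (j in seq_len(nrow(tc))) {
      u <- c(cos(arc$phi[idx[j]]), sin(arc$phi[idx[j]]))
      tv <- c(-u[2], u[1])
      half_diag <- sqrt(wv^2 + hv^2) / 2
      cxx <- tc$x[j]; cyy <- tc$y[j]
      xr <- max(1L, floor(cxx - half_diag)):min(w, ceiling(cxx + half_diag))
      yr <- max(1L, floor(cyy - half_diag)):min(h, ceiling(cyy + half_diag))
      px <- outer(rep(1, length(yr)), xr - 0.5)   # x of pixel centres
      py <- outer(yr - 0.5, rep(1, length(xr)))   # y of pixel centres
      du <- (px - cxx) * u[1] + (py - cyy) * u[2]
      dt <- (px - cxx) * tv[1] + (py - cyy) * tv[2]
      inside <- abs(du) <= wv / 2 & abs(dt) <= hv / 2
      block <- img[yr, xr, drop = FALSE]
      block[inside] <- body_intensity
      img[yr, xr] <- block
    }
  }

  img <- gaussian_blur(img, spec$blur_sigma)
  if (spec$background_noise_sd > 0) {
    img <- img + with_seed(child_seed(spec$seed, 2L),
                           matrix(stats::rnorm(h * w, 0, spec$background_noise_sd),
                                  nrow = h))
  }
  img <- pmin(pmax(img, 0), 1)

  ann <- if (nrow(tc)) {
    yolo_lines(truth$true_boxes, image_size = spec$image_size)
  } else {
    character(0)
  }
  list(image = img, boxes = truth$true_boxes, annotation = ann)
}

#' Write a `[0, 1]` intensity matrix as plain-text PGM (P2)
#'
#' @param img Numeric matrix with values in `[0, 1]`.
#' @param path Output path.
#' @param maxval Grey-level quantisation (default 255).
#' @return `path`, invisibly.
#' @export
write_pgm <- function(img, path, maxval = 255L) {
  stopifnot(is.matrix(img))
  q <- round(pmin(pmax(img, 0), 1) * maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), as.character(maxval)), con)
  utils::write.table(q, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a plain-text PGM (P2) image as a `[0, 1]` matrix
#'
#' @param path PGM file path.
#' @return Numeric matrix (rows = y) with values in `[0, 1]`.
#' @export
read_pgm <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  if (!identical(trimws(lines[1]), "P2")) {
    abort("not a plain-text PGM (P2) file", "parse_error")
  }
  tokens <- as.numeric(unlist(strsplit(paste(lines[-1], collapse = " "), "\\s+")))
  tokens <- tokens[!is.na(tokens)]
  w <- tokens[1]; h <- tokens[2]; maxval <- tokens[3]
  px <- tokens[-(1:3)]
  if (length(px) != w * h) abort("truncated PGM pixel data", "parse_error")
  matrix(px, nrow = h, ncol = w, byrow = TRUE) / maxval
}
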