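# Vertebral levels and centroid sets.
#
# The measurement substrate is the chain of Th4..Th12 vertebral-body
# centroids on a lateral thoracic spine image. Coordinates are image
# coordinates (origin top-left, x rightward, y caudally, 0-based pixels);
# all angle computations downstream are invariant to this convention.

#' Thoracic vertebral levels Th4 to Th12
#'
#' The nine thoracic levels used for curvature estimation, ordered
#' cranial to caudal (Th4 first).
#'
#' @return Character vector `c("Th4", ..., "Th12")`.
#' @export
#' @examples
#' thoracic_levels()
thoracic_levels <- function() {
  paste0("Th", 4:12)
}

#' Construct a vertebral centroid set
#'
#' Holds per-level centroid coordinates and detection confidences for one
#' scan. Rows are stored in cranial-to-caudal order regardless of input
#' order; at most one entry per level is allowed.
#'
#' @param level Character vector of levels among `thoracic_levels()`.
#' @param x,y Numeric centroid coordinates (same unit throughout the scan).
#' @param confidence Detection confidence in `[0, 1]` (default 1).
#' @param scan_id Scan identifier string.
#' @param units Coordinate unit tag, `"px"` or `"mm"`.
#' @return An object of class `vertebral_centroids`: a data frame with
#'   columns `level`, `x`, `y`, `confidence` plus attributes `scan_id`
#'   and `units`.
#' @export
#' @examples
#' vc <- vertebral_centroids(thoracic_levels(), x = rep(100, 9),
#'                           y = seq(50, 450, length.out = 9))
#' is_complete(vc)
vertebral_centroids <- function(level, x, y, confidence = 1,
                                scan_id = "scan", units = c("px", "mm")) {
  units <- match.arg(units)
  level <- as.character(level)
  known <- thoracic_levels()
  if (!all(level %in% known)) {
    abort(sprintf("unknown vertebral level(s): %s",
                  paste(setdiff(level, known), collapse = ", ")),
          "level_error")
  }
  if (anyDuplicated(level)) {
    abort("duplicate vertebral levels in centroid set", "level_error")
  }
  n <- length(level)
  x <- as.numeric(x)
  y <- as.numeric(y)
  confidence <- rep_len(as.numeric(confidence), n)
  if (length(x) != n || length(y) != n) {
    abort("level, x and y must have equal length", "level_error")
  }
  if (n && (!all(is.finite(x)) || !all(is.finite(y)))) {
    abort("non-finite centroid coordinates", "coordinate_error")
  }
  if (n && any(confidence < 0 | confidence > 1, na.rm = TRUE)) {
    abort("confidence must lie in [0, 1]", "coordinate_error")
  }
  ord <- order(match(level, known))
  out <- data.frame(level = level[ord], x = x[ord], y = y[ord],
                    confidence = confidence[ord],
                    stringsAsFactors = FALSE)
  structure(out, scan_id = as.character(scan_id), units = units,
            class = c("vertebral_centroids", "data.frame"))
}

#' Is a centroid set complete?
#'
#' @param centroids A [vertebral_centroids()] object.
#' @return `TRUE` iff all nine levels Th4-Th12 are present.
#' @export
is_complete <- function(centroids) {
  stopifnot(inherits(centroids, "vertebral_centroids"))
  all(thoracic_levels() %in% centroids$level)
}

missing_levels <- function(centroids) {
  setdiff(thoracic_levels(), centroids$level)
}

#' @export
print.vertebral_centroids <- function(x, ...) {
  cat(sprintf("Vertebral centroid set '%s' (%s): %d/9 levels\n",
              attr(x, "scan_id"), attr(x, "units"), nrow(x)))
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' Read vertebral centroids from CSV
#'
#' Expects a header row and columns `scan_id`, `level`, `x`, `y`,
#' `confidence` (UTF-8). Several scans may share one file; one
#' `vertebral_centroids` object is returned per `scan_id`.
#'
#' @param path CSV file path.
#' @param units Coordinate unit tag for all scans in the file.
#' @return Named list of [vertebral_centroids()] objects, one per scan.
#' @export
read_centroids <- function(path, units = "px") {
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8"),
    error = function(e) abort(sprintf("cannot parse centroid CSV: %s",
                                      conditionMessage(e)), "parse_error")
  )
  need <- c("scan_id", "level", "x", "y")
  if (!all(need %in% names(df))) {
    abort(sprintf("centroid CSV must have columns %s",
                  paste(need, collapse = ", ")), "parse_error")
  }
  if (is.null(df$confidence)) df$confidence <- 1
  if (!is.numeric(df$x) || !is.numeric(df$y)) {
    abort("centroid CSV columns x and y must be numeric", "parse_error")
  }
  out <- lapply(split(df, df$scan_id), function(d) {
    vertebral_centroids(d$level, d$x, d$y, d$confidence,
                        scan_id = d$scan_id[1], units = units)
  })
  out[unique(df$scan_id)]
}

#' Write vertebral centroids to CSV
#'
#' @param centroids A [vertebral_centroids()] object or a list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_centroids <- function(centroids, path) {
  if (inherits(centroids, "vertebral_centroids")) centroids <- list(centroids)
  rows <- lapply(centroids, function(vc) {
    cbind(scan_id = attr(vc, "scan_id"), as.data.frame(vc))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
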