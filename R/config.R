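# Run configuration shared by the CLI subcommands.

#' Pipeline run configuration
#'
#' Bundles the clinical and evaluation thresholds: >= 40 degrees for
#' clinically significant kyphosis, IoU >= 0.5 for detection success, and
#' the 2-degree inter-observer consensus rule. Serialises losslessly to
#' JSON via [write_run_config()] / [read_run_config()].
#'
#' @param threshold_deg Kyphosis classification threshold in degrees.
#' @param iou_threshold Detection-matching IoU criterion.
#' @param fit_method Circle-fit method, `"geometric"` (default) or
#'   `"algebraic"`.
#' @param consensus_threshold_deg Inter-observer consensus threshold.
#' @param seed Optional integer seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(threshold_deg = 40, iou_threshold = 0.5,
                       fit_method = c("geometric", "algebraic"),
                       consensus_threshold_deg = 2, seed = NULL) {
  fit_method <- match.arg(fit_method)
  if (threshold_deg <= 0 || iou_threshold <= 0 || consensus_threshold_deg <= 0) {
    abort("thresholds must be positive", "spec_error")
  }
  structure(list(threshold_deg = threshold_deg,
                 iou_threshold = iou_threshold,
                 fit_method = fit_method,
                 consensus_threshold_deg = consensus_threshold_deg,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config` object.
#' @param path JSON path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                error = function(e) abort(sprintf("cannot parse config: %s",
                                                  conditionMessage(e)),
                                          "parse_error"))
  do.call(run_config, x[intersect(names(x), names(formals(run_config)))])
}
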