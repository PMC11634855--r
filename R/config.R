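#' Default run configuration
#'
#' Bundles the calibration, enhancement, detection and evaluation
#' parameters used by the command wrappers.  All values mirror the
#' reference pipeline defaults.
#'
#' @return A nested list of class `run_config` with elements `calibration`,
#'   `enhance`, `detect` (micrometre gates plus Canny/vote thresholds) and
#'   `eval` (matching `tolerance_um`).
#' @export
default_run_config <- function() {
  structure(list(
    calibration = list(px_per_um = 26.3, spatial_resolution_um = 2.19),
    enhance = list(gaussian_kernel = 5L, gaussian_sigma = NULL,
                   median_window = 5L, clahe_clip_limit = 1.0,
                   clahe_grid = 8L, brightness_bias = 7,
                   contrast_scale = 1.02, resize_side = 501L,
                   brightness_first = TRUE),
    detect = list(min_radius_um = 2.5, max_radius_um = 5.0,
                  min_separation_um = 4.5, canny_high = 100,
                  canny_low = 50, vote_threshold = 18,
                  use_raw_scale = FALSE),
    eval = list(tolerance_um = 3.0),
    log_level = "info"
  ), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Keys mirror the [default_run_config()] structure; values present in the
#' file override the defaults, everything else keeps its default.  The
#' merged configuration is validated; invalid values raise a condition of
#' class `config_error`.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) {
      sc_stop("config_error", paste0("config file not found: ", path))
    }
    user <- yaml::read_yaml(path)
    for (section in intersect(names(user), names(cfg))) {
      if (is.list(user[[section]])) {
        for (key in names(user[[section]])) {
          cfg[[section]][[key]] <- user[[section]][[key]]
        }
      } else {
        cfg[[section]] <- user[[section]]
      }
    }
  }
  validate_run_config(cfg)
}

#' Validate a run configuration
#'
#' @param cfg a `run_config` list.
#' @return `cfg`, invisibly classed, if valid; otherwise a `config_error`
#'   condition is raised.
#' @export
validate_run_config <- function(cfg) {
  as_config_error <- function(expr) {
    tryCatch(expr, smearcount_error = function(e) {
      sc_stop("config_error", conditionMessage(e))
    }, error = function(e) {
      sc_stop("config_error", conditionMessage(e))
    })
  }
  as_config_error(do.call(optical_calibration, cfg$calibration))
  as_config_error(do.call(enhance_params, cfg$enhance))
  as_config_error(detection_params_um(cfg$detect$min_radius_um,
                                      cfg$detect$max_radius_um,
                                      cfg$detect$min_separation_um))
  if (!is.numeric(cfg$eval$tolerance_um) || cfg$eval$tolerance_um <= 0) {
    sc_stop("config_error", "eval tolerance_um must be positive")
  }
  if (!is.numeric(cfg$detect$canny_high) || cfg$detect$canny_high <= 0 ||
      !is.numeric(cfg$detect$vote_threshold) ||
      cfg$detect$vote_threshold <= 0) {
    sc_stop("config_error", "detection thresholds must be positive")
  }
  structure(cfg, class = "run_config")
}
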