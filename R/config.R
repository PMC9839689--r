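# Measurement configuration: the tunable thresholds of the pipeline.

#' Measurement pipeline configuration
#'
#' Collects the quality-control thresholds and numerical options of the
#' measurement pipeline.
#'
#' @param frame_fill_warn Warn when the wound mask covers less than this
#'   fraction of the frame (default 0.20; small, distant wounds segment
#'   and measure unreliably).
#' @param min_cos_theta Error when the fitted plane's tilt cosine falls
#'   below this (default 0.1, i.e. planes steeper than about 84 degrees),
#'   where the 1/cos rescaling amplifies noise without bound.
#' @param contour_step Keep every k-th contour vertex before
#'   back-projection (default 1 = keep all).
#' @param max_drop_fraction Error when more than this fraction of contour
#'   vertices has no valid depth (default 0.5).
#' @param boundary_correction Multiply the measured area by the ratio of
#'   the traced component's pixel count to the 2D shoelace area of its
#'   pixel-centre contour, correcting the half-pixel under-measurement
#'   inherent in tracing boundary-pixel centres (default TRUE; only
#'   applies to mask inputs).
#' @param resize_to Optional target size (single integer, e.g. 512) to
#'   which file-level inputs are resized before measuring; NULL disables.
#' @param depth_scale Metres per stored unit when reading integer depth
#'   images (default 1e-3: millimetre-encoded 16-bit PNG).
#' @param invalid_value Stored depth value treated as "no return"
#'   (default 0).
#' @return An object of class `"measurement_config"` (a validated list).
#' @export
measurement_config <- function(frame_fill_warn = 0.20,
                               min_cos_theta = 0.10,
                               contour_step = 1L,
                               max_drop_fraction = 0.5,
                               boundary_correction = TRUE,
                               resize_to = NULL,
                               depth_scale = 1e-3,
                               invalid_value = 0) {
  check_number(frame_fill_warn, "frame_fill_warn")
  if (frame_fill_warn < 0 || frame_fill_warn > 1) {
    stop_wa("`frame_fill_warn` must be in [0, 1]", "wa_input_error")
  }
  check_number(min_cos_theta, "min_cos_theta", positive = TRUE)
  if (min_cos_theta > 1) {
    stop_wa("`min_cos_theta` must be in (0, 1]", "wa_input_error")
  }
  contour_step <- as.integer(contour_step)
  if (is.na(contour_step) || contour_step < 1L) {
    stop_wa("`contour_step` must be a positive integer", "wa_input_error")
  }
  check_number(max_drop_fraction, "max_drop_fraction")
  if (max_drop_fraction < 0 || max_drop_fraction > 1) {
    stop_wa("`max_drop_fraction` must be in [0, 1]", "wa_input_error")
  }
  if (!is.logical(boundary_correction) || length(boundary_correction) != 1L) {
    stop_wa("`boundary_correction` must be TRUE or FALSE", "wa_input_error")
  }
  if (!is.null(resize_to)) {
    check_number(resize_to, "resize_to", positive = TRUE)
    resize_to <- as.integer(resize_to)
  }
  check_number(depth_scale, "depth_scale", positive = TRUE)
  check_number(invalid_value, "invalid_value")
  structure(list(
    frame_fill_warn = frame_fill_warn,
    min_cos_theta = min_cos_theta,
    contour_step = contour_step,
    max_drop_fraction = max_drop_fraction,
    boundary_correction = boundary_correction,
    resize_to = resize_to,
    depth_scale = depth_scale,
    invalid_value = invalid_value
  ), class = "measurement_config")
}

#' @export
print.measurement_config <- function(x, ...) {
  cat("Measurement configuration:\n")
  cat(sprintf("  frame-fill warning below: %.0f%%\n", 100 * x$frame_fill_warn))
  cat(sprintf("  steep-plane guard: cos(theta) >= %.2f\n", x$min_cos_theta))
  cat(sprintf("  contour step: %d, max dropped vertices: %.0f%%\n",
              x$contour_step, 100 * x$max_drop_fraction))
  cat(sprintf("  boundary correction: %s\n", x$boundary_correction))
  cat(sprintf("  resize to: %s\n",
              if (is.null(x$resize_to)) "off" else x$resize_to))
  cat(sprintf("  depth scale: %g m/unit, invalid value: %g\n",
              x$depth_scale, x$invalid_value))
  invisible(x)
}

# Lossless (list) representation for JSON round-tripping.
config_to_list <- function(cfg) {
  unclass(cfg)
}

config_from_list <- function(lst) {
  do.call(measurement_config, lst)
}
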