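#' Raw capture container
#'
#' Wraps an 8-bit photograph as taken by the phone camera.  `pixels` is an
#' integer matrix (grayscale) or a height x width x 3 integer array (RGB),
#' values in `[0, 255]`.  Both image dimensions must be at least 32 px.
#'
#' @param pixels numeric/integer matrix or 3-channel array of intensities.
#' @return An object of class `raw_image` with elements `pixels`, `height`,
#'   `width` and `channels`.
#' @export
raw_image <- function(pixels) {
  if (is.matrix(pixels)) {
    channels <- 1L
  } else if (is.array(pixels) && length(dim(pixels)) == 3L &&
             dim(pixels)[3L] %in% c(1L, 3L)) {
    channels <- dim(pixels)[3L]
    if (channels == 1L) {
      pixels <- pixels[, , 1L]
    }
  } else {
    sc_stop("channel_error",
            "pixels must be a matrix or an array with 1 or 3 channels")
  }
  if (anyNA(pixels)) {
    sc_stop("value_error", "pixel intensities must not be missing")
  }
  rng <- range(pixels)
  if (rng[1L] < 0 || rng[2L] > 255) {
    sc_stop("value_error", "pixel intensities must lie in [0, 255]")
  }
  storage.mode(pixels) <- "integer"
  h <- dim(pixels)[1L]; w <- dim(pixels)[2L]
  if (h < 32L || w < 32L) {
    sc_stop("value_error", "image must be at least 32 x 32 pixels")
  }
  structure(list(pixels = pixels, height = h, width = w,
                 channels = if (is.matrix(pixels)) 1L else 3L),
            class = "raw_image")
}

#' @export
print.raw_image <- function(x, ...) {
  cat(sprintf("<raw_image %d x %d, %d channel(s)>\n",
              x$height, x$width, x$channels))
  invisible(x)
}

# accept raw_image (1 channel) or a bare matrix; return integer matrix
as_px_matrix <- function(img) {
  if (inherits(img, "raw_image")) {
    if (img$channels != 1L) {
      sc_stop("channel_error", "a single-channel image is required here")
    }
    return(img$pixels)
  }
  if (is.matrix(img)) {
    m <- img
    storage.mode(m) <- "integer"
    return(m)
  }
  sc_stop("value_error", "expected a raw_image or an intensity matrix")
}

#' Field-of-view geometry
#'
#' The circular bright region visible through the microscope optics, in
#' pixel coordinates of the image it was estimated from.
#'
#' @param center_row,center_col circle center (px, 1-based).
#' @param radius circle radius (px), positive.
#' @param image_dim optional `c(height, width)`; when given, the circle is
#'   checked to lie fully inside the image.
#' @return An object of class `fov_geometry`.
#' @export
fov_geometry <- function(center_row, center_col, radius, image_dim = NULL) {
  if (radius <= 0) sc_stop("value_error", "FOV radius must be positive")
  if (!is.null(image_dim)) {
    h <- image_dim[1L]; w <- image_dim[2L]
    if (center_row - radius < 0.5 || center_row + radius > h + 0.5 ||
        center_col - radius < 0.5 || center_col + radius > w + 0.5) {
      sc_stop("value_error", "FOV circle must lie inside the image")
    }
  }
  structure(list(center_row = center_row, center_col = center_col,
                 radius = radius),
            class = "fov_geometry")
}

#' Optical calibration of the microscope attachment
#'
#' @param px_per_um pixel resolution of the raw capture (px per micrometre).
#'   The reference device resolves 26.3 px/um.
#' @param spatial_resolution_um smallest optically resolvable feature (um);
#'   informational only, not used in any computation.
#' @return An object of class `optical_calibration`.
#' @export
optical_calibration <- function(px_per_um = 26.3, spatial_resolution_um = 2.19) {
  if (px_per_um <= 0) sc_stop("value_error", "px_per_um must be positive")
  structure(list(px_per_um = px_per_um,
                 spatial_resolution_um = spatial_resolution_um),
            class = "optical_calibration")
}

#' Pixel-scale bookkeeping across the resize stage
#'
#' Records the raw capture resolution, the resize factor applied by
#' [resize_tracked()] and the resulting effective resolution.  The identity
#' `effective_px_per_um == raw_px_per_um * resize_factor` holds exactly by
#' construction; it is the bridge between micrometre detection parameters
#' and pixel-space algorithms.
#'
#' @param raw_px_per_um resolution of the image entering the resize (px/um).
#' @param resize_factor target side divided by input side (dimensionless).
#' @return An object of class `scale_state`.
#' @export
scale_state <- function(raw_px_per_um, resize_factor = 1) {
  if (raw_px_per_um <= 0 || resize_factor <= 0) {
    sc_stop("value_error", "scale fields must be positive")
  }
  structure(list(raw_px_per_um = raw_px_per_um,
                 resize_factor = resize_factor,
                 effective_px_per_um = raw_px_per_um * resize_factor),
            class = "scale_state")
}

#' Enhancement-chain parameters
#'
#' Defaults reproduce the reference chain: 5x5 Gaussian smoothing, the 3x3
#' sharpening stencil (all -1 with center 9; entries sum to 1), a 5x5 median
#' filter, CLAHE with clip limit 1.0 on an 8x8 tile grid, then brightness
#' bias +7 and contrast scaling 1.02, on a 501x501 working image.
#'
#' @param gaussian_kernel odd Gaussian kernel side (px), >= 3.
#' @param gaussian_sigma Gaussian standard deviation; `NULL` derives it from
#'   the kernel size as `0.3 * ((k - 1)/2 - 1) + 0.8` (1.1 for k = 5).
#' @param median_window odd median window side (px), >= 3.
#' @param clahe_clip_limit CLAHE clip limit as a multiple of the uniform
#'   per-tile histogram level; positive.
#' @param clahe_grid CLAHE tiles per image side, >= 1.
#' @param brightness_bias constant added to intensities (8-bit units).
#' @param contrast_scale multiplicative contrast factor.
#' @param resize_side working-image side length (px), >= 64.
#' @param brightness_first apply the bias before the contrast scaling
#'   (the reference order); `FALSE` swaps the two.
#' @return An object of class `enhance_params`.
#' @export
enhance_params <- function(gaussian_kernel = 5L, gaussian_sigma = NULL,
                           median_window = 5L, clahe_clip_limit = 1.0,
                           clahe_grid = 8L, brightness_bias = 7,
                           contrast_scale = 1.02, resize_side = 501L,
                           brightness_first = TRUE) {
  odd_ok <- function(k) k >= 3L && k %% 2L == 1L
  if (!odd_ok(gaussian_kernel) || !odd_ok(median_window)) {
    sc_stop("value_error", "filter windows must be odd and >= 3")
  }
  if (clahe_clip_limit <= 0 || clahe_grid < 1L) {
    sc_stop("value_error", "invalid CLAHE parameters")
  }
  if (resize_side < 64L) sc_stop("value_error", "resize_side must be >= 64")
  if (is.null(gaussian_sigma)) {
    gaussian_sigma <- 0.3 * ((gaussian_kernel - 1) / 2 - 1) + 0.8
  }
  stencil <- matrix(-1L, 3L, 3L); stencil[2L, 2L] <- 9L
  structure(list(gaussian_kernel = as.integer(gaussian_kernel),
                 gaussian_sigma = gaussian_sigma,
                 sharpen_kernel = stencil,
                 median_window = as.integer(median_window),
                 clahe_clip_limit = clahe_clip_limit,
                 clahe_grid = as.integer(clahe_grid),
                 brightness_bias = brightness_bias,
                 contrast_scale = contrast_scale,
                 resize_side = as.integer(resize_side),
                 brightness_first = isTRUE(brightness_first)),
            class = "enhance_params")
}

#' Processed working image
#'
#' Output of [preprocess()]: the enhanced square grayscale image, its
#' field-of-view mask (pixels outside are zero), the [scale_state()] tying
#' pixels back to micrometres, and the ordered list of stages applied.
#'
#' @param pixels integer matrix, `resize_side` x `resize_side`.
#' @param fov_mask logical matrix of the same shape.
#' @param scale a [scale_state()].
#' @param provenance character vector of stage names in application order.
#' @param crop_origin 1-based (row, col) of the crop's top-left pixel in
#'   the raw frame; together with `scale$resize_factor` it maps raw-frame
#'   annotations into this image's coordinates.
#' @return An object of class `processed_image`.
#' @export
processed_image <- function(pixels, fov_mask, scale, provenance,
                            crop_origin = c(1L, 1L)) {
  storage.mode(pixels) <- "integer"
  if (!identical(dim(pixels), dim(fov_mask))) {
    sc_stop("value_error", "pixels and fov_mask shapes differ")
  }
  if (nrow(pixels) != ncol(pixels)) {
    sc_stop("value_error", "processed image must be square")
  }
  if (any(pixels[!fov_mask] != 0L)) {
    sc_stop("value_error", "pixels outside the FOV mask must be zero")
  }
  structure(list(pixels = pixels, fov_mask = fov_mask, scale = scale,
                 provenance = provenance,
                 crop_origin = as.integer(crop_origin)),
            class = "processed_image")
}

#' @export
print.processed_image <- function(x, ...) {
  cat(sprintf("<processed_image %d x %d, %.4g px/um effective, stages: %s>\n",
              nrow(x$pixels), ncol(x$pixels), x$scale$effective_px_per_um,
              paste(x$provenance, collapse = " -> ")))
  invisible(x)
}

#' Detection parameters in micrometres
#'
#' Physical-unit Hough parameters: erythrocytes are gated to radii between
#' `min_radius_um` and `max_radius_um` (defaults 2.5 and 5 um) and accepted
#' detections must be at least `min_separation_um` apart (default 4.5 um).
#'
#' @param min_radius_um,max_radius_um radius gate (um), `0 < min < max`.
#' @param min_separation_um minimum center separation (um), positive.
#' @return An object of class `detection_params_um`.
#' @export
detection_params_um <- function(min_radius_um = 2.5, max_radius_um = 5.0,
                                min_separation_um = 4.5) {
  if (!(min_radius_um > 0 && min_radius_um < max_radius_um)) {
    sc_stop("value_error", "need 0 < min_radius_um < max_radius_um")
  }
  if (min_separation_um <= 0) {
    sc_stop("value_error", "min_separation_um must be positive")
  }
  structure(list(min_radius_um = min_radius_um,
                 max_radius_um = max_radius_um,
                 min_separation_um = min_separation_um),
            class = "detection_params_um")
}

#' Detection parameters in pixels
#'
#' Pixel-space counterpart of [detection_params_um()], normally produced by
#' [to_px_params()].  Canny thresholds apply to unnormalized Sobel gradient
#' magnitudes of the 8-bit image; `vote_threshold` is the minimum center
#' accumulator count for a circle candidate.
#'
#' @param min_radius_px,max_radius_px integer radius gate (px).
#' @param min_separation_px minimum center separation (px).
#' @param canny_high,canny_low Canny hysteresis thresholds; `canny_low`
#'   defaults to half of `canny_high`.
#' @param vote_threshold minimum accumulator votes for a candidate center.
#' @return An object of class `detection_params_px`.
#' @export
detection_params_px <- function(min_radius_px, max_radius_px,
                                min_separation_px, canny_high = 100,
                                canny_low = canny_high / 2,
                                vote_threshold = 18) {
  if (min_radius_px < 1L) {
    sc_stop("scale_error",
            "minimum radius is below 1 px: image too coarse for the cell size")
  }
  if (max_radius_px < min_radius_px || min_separation_px <= 0 ||
      canny_high <= 0 || canny_low <= 0 || vote_threshold <= 0) {
    sc_stop("value_error", "invalid pixel detection parameters")
  }
  structure(list(min_radius_px = as.integer(min_radius_px),
                 max_radius_px = as.integer(max_radius_px),
                 min_separation_px = min_separation_px,
                 canny_high = canny_high, canny_low = canny_low,
                 vote_threshold = vote_threshold),
            class = "detection_params_px")
}

# canonical empty circle table
empty_circles <- function() {
  data.frame(center_row = numeric(0), center_col = numeric(0),
             radius_px = numeric(0), votes = numeric(0))
}
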