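#' Otsu threshold of an 8-bit intensity image
#'
#' Maximizes the between-class variance over the 256-bin integer
#' histogram; returns the integer level `t` such that foreground is
#' `v > t`.  Agrees with the usual implementations on 8-bit data.
#'
#' @param g integer intensity matrix in `[0, 255]`.
#' @return Integer threshold in `[0, 254]`.
#' @export
otsu_threshold <- function(g) {
  counts <- as.numeric(tabulate(as.vector(g) + 1L, 256L))
  n <- sum(counts)
  lev <- as.numeric(0:255)
  w0 <- cumsum(counts)
  mu <- cumsum(counts * lev)
  mu_t <- mu[256L]
  t_cand <- 1:255  # split after level t-1
  w0c <- w0[t_cand]; w1c <- n - w0c
  ok <- w0c > 0 & w1c > 0
  between <- rep(-Inf, 255L)
  between[ok] <- (mu_t * w0c[ok] / n - mu[t_cand][ok])^2 /
    (w0c[ok] / n * w1c[ok] / n)
  which.max(between) - 1L
}

#' Estimate the field-of-view circle of a capture
#'
#' The bright circular field of view is located by global Otsu thresholding,
#' keeping the largest 4-connected bright component, and taking the minimal
#' enclosing circle of its boundary pixels.  The circle is clipped so it
#' lies fully inside the image.
#'
#' @param raw a [raw_image()] (RGB inputs are converted to luma first).
#' @return A [fov_geometry()].
#' @export
estimate_fov <- function(raw) {
  g <- if (inherits(raw, "raw_image") && raw$channels == 3L) {
    as_px_matrix(to_gray(raw))
  } else {
    as_px_matrix(raw)
  }
  h <- nrow(g); w <- ncol(g)
  rng <- range(g)
  if (rng[1L] == rng[2L]) {
    sc_stop("no_fov_error", "image is constant: no bright region found")
  }
  thr <- otsu_threshold(g)
  bw <- g > thr
  comp <- cpp_largest_component4(bw)
  if (comp$size < 0.01 * h * w) {
    sc_stop("no_fov_error",
            "no bright component covers at least 1% of the image")
  }
  bnd <- comp$boundary
  hull <- grDevices::chull(bnd[, 2L], bnd[, 1L])
  mec <- min_enclosing_circle(bnd[hull, , drop = FALSE])
  cr <- mec$center[1L]; cc <- mec$center[2L]
  r <- min(mec$radius, cr - 0.5, cc - 0.5, h - cr + 0.5, w - cc + 0.5)
  fov_geometry(cr, cc, r, image_dim = c(h, w))
}

#' Crop a capture to the square around its field of view
#'
#' Side length is `min(2 * fov radius, height, width)`; the crop is centered
#' on the FOV center and shifted minimally to stay inside the image.
#'
#' @param raw a [raw_image()].
#' @param fov a [fov_geometry()] valid for `raw`.
#' @return A [raw_image()] carrying an `origin` attribute, the 1-based
#'   (row, col) of the crop's top-left pixel in the input frame.
#' @export
crop_square <- function(raw, fov) {
  h <- raw$height; w <- raw$width
  side <- as.integer(min(round_half_up(2 * fov$radius), h, w))
  start_row <- as.integer(min(max(round_half_up(fov$center_row - side / 2), 1L),
                              h - side + 1L))
  start_col <- as.integer(min(max(round_half_up(fov$center_col - side / 2), 1L),
                              w - side + 1L))
  rows <- start_row:(start_row + side - 1L)
  cols <- start_col:(start_col + side - 1L)
  px <- if (raw$channels == 3L) raw$pixels[rows, cols, , drop = FALSE]
        else raw$pixels[rows, cols, drop = FALSE]
  out <- raw_image(px)
  attr(out, "origin") <- c(start_row, start_col)
  out
}

#' Convert an RGB capture to grayscale
#'
#' BT.601 luma weights (0.299, 0.587, 0.114 for R, G, B), rounded half-up.
#' Single-channel inputs are returned unchanged.
#'
#' @param img a [raw_image()] with 1 or 3 channels.
#' @return A single-channel [raw_image()].
#' @export
to_gray <- function(img) {
  if (!inherits(img, "raw_image")) img <- raw_image(img)
  if (img$channels == 1L) return(img)
  if (img$channels != 3L) {
    sc_stop("channel_error", "grayscale conversion needs 1 or 3 channels")
  }
  out <- raw_image(cpp_luma(img$pixels[, , 1L], img$pixels[, , 2L],
                            img$pixels[, , 3L]))
  attr(out, "origin") <- attr(img, "origin")
  out
}

#' Min-max normalization over the field-of-view mask
#'
#' Intensities inside the mask are affinely mapped so the masked minimum
#' becomes 0 and the masked maximum 255 (half-up rounding); pixels outside
#' the mask are set to 0.
#'
#' @param gray single-channel [raw_image()] or intensity matrix.
#' @param mask logical matrix of the same shape with at least one `TRUE`.
#' @return Same container type as `gray`.
#' @export
normalize_in_mask <- function(gray, mask) {
  g <- as_px_matrix(gray)
  if (!identical(dim(g), dim(mask))) {
    sc_stop("value_error", "mask shape must match the image")
  }
  if (!any(mask)) sc_stop("value_error", "mask has no TRUE pixels")
  v <- g[mask]
  m <- min(v); M <- max(v)
  if (M == m) {
    sc_stop("degenerate_image_error",
            "constant intensity inside the FOV: blank capture")
  }
  out <- g
  out[mask] <- as.integer(round_half_up(255 * (v - m) / (M - m)))
  out[!mask] <- 0L
  if (inherits(gray, "raw_image")) raw_image(out) else out
}

# sparse row-weight matrix for exact area-average (box) downscaling
box_weight_matrix <- function(n_in, n_out) {
  f <- n_in / n_out
  ii <- integer(0); jj <- integer(0); ww <- numeric(0)
  for (i in seq_len(n_out)) {
    lo <- (i - 1) * f; hi <- i * f
    j <- (floor(lo) + 1L):ceiling(hi)
    j <- j[j >= 1L & j <= n_in]
    overlap <- pmin(j, hi) - pmax(j - 1, lo)
    keep <- overlap > 1e-12
    ii <- c(ii, rep(i, sum(keep))); jj <- c(jj, j[keep])
    ww <- c(ww, overlap[keep] / f)
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = ww, dims = c(n_out, n_in))
}

# sparse two-tap bilinear weight matrix (used only for upscales)
bilinear_weight_matrix <- function(n_in, n_out) {
  f <- n_in / n_out
  src <- (seq_len(n_out) - 0.5) * f + 0.5
  j0 <- pmin(pmax(floor(src), 1), n_in)
  j1 <- pmin(j0 + 1, n_in)
  w1 <- pmin(pmax(src - j0, 0), 1)
  Matrix::sparseMatrix(i = rep(seq_len(n_out), 2L), j = c(j0, j1),
                       x = c(1 - w1, w1), dims = c(n_out, n_in))
}

#' Resize a square image while tracking the physical scale
#'
#' Downscaling uses exact area averaging (box filter); the mask is
#' resampled with a >= 0.5 coverage rule.  Upscaling (rare; emits a
#' warning) uses bilinear interpolation.  The returned [scale_state()]
#' satisfies `effective_px_per_um = px_per_um * side / input_side` exactly.
#'
#' @param gray single-channel square [raw_image()] or matrix.
#' @param mask logical matrix matching `gray`.
#' @param calib an [optical_calibration()] for the input image.
#' @param side target side length (px), >= 64.
#' @return `list(image, mask, scale)`.
#' @export
resize_tracked <- function(gray, mask, calib, side = 501L) {
  g <- as_px_matrix(gray)
  n <- nrow(g)
  if (n != ncol(g)) sc_stop("value_error", "resize input must be square")
  if (side < 64L) sc_stop("value_error", "target side must be >= 64 px")
  scale <- scale_state(calib$px_per_um, side / n)
  if (side == n) {
    return(list(image = g, mask = mask, scale = scale))
  }
  W <- if (side < n) {
    box_weight_matrix(n, side)
  } else {
    warning("upscaling requested; using bilinear interpolation",
            call. = FALSE)
    bilinear_weight_matrix(n, side)
  }
  img_out <- quantize8(as.matrix(W %*% g %*% Matrix::t(W)))
  cov <- as.matrix(W %*% (mask * 1) %*% Matrix::t(W))
  list(image = img_out, mask = cov >= 0.5, scale = scale)
}

#' Gaussian smoothing
#'
#' Separable convolution with a sampled, normalized Gaussian kernel and
#' reflect-101 borders; re-quantized half-up to 8 bits.
#'
#' @param img single-channel [raw_image()] or matrix.
#' @param kernel odd kernel side (px).
#' @param sigma standard deviation; `NULL` uses `0.3*((k-1)/2 - 1) + 0.8`.
#' @return Intensity matrix.
#' @export
gaussian_smooth <- function(img, kernel = 5L, sigma = NULL) {
  g <- as_px_matrix(img)
  if (is.null(sigma)) sigma <- 0.3 * ((kernel - 1) / 2 - 1) + 0.8
  half <- (kernel - 1L) %/% 2L
  x <- seq(-half, half)
  k <- exp(-x^2 / (2 * sigma^2))
  k <- k / sum(k)
  conv1 <- function(m, along_rows) {
    n <- if (along_rows) nrow(m) else ncol(m)
    idx <- reflect101_index(seq(1L - half, n + half), n)
    out <- 0
    for (t in seq_len(kernel)) {
      sl <- idx[t:(t + n - 1L)]
      out <- out + k[t] * (if (along_rows) m[sl, , drop = FALSE]
                           else m[, sl, drop = FALSE])
    }
    out
  }
  quantize8(conv1(conv1(g, TRUE), FALSE))
}

#' Edge sharpening with the 3x3 stencil
#'
#' Convolution with the stencil whose entries are all -1 with center 9
#' (sum 1, so constants are preserved); reflect-101 borders, result
#' clipped to `[0, 255]`.
#'
#' @param img single-channel [raw_image()] or matrix.
#' @return Intensity matrix.
#' @export
sharpen_filter <- function(img) {
  g <- as_px_matrix(img)
  h <- nrow(g); w <- ncol(g)
  ri <- reflect101_index(0:(h + 1L), h)
  ci <- reflect101_index(0:(w + 1L), w)
  p <- g[ri, ci, drop = FALSE]  # (h+2) x (w+2) padded
  neigh <- p[1:h, 1:w] + p[1:h, 2:(w + 1L)] + p[1:h, 3:(w + 2L)] +
    p[2:(h + 1L), 1:w] + p[2:(h + 1L), 3:(w + 2L)] +
    p[3:(h + 2L), 1:w] + p[3:(h + 2L), 2:(w + 1L)] + p[3:(h + 2L), 3:(w + 2L)]
  quantize8(9 * g - neigh)
}

#' Median filtering
#'
#' Square-window median with reflect-101 borders.
#'
#' @param img single-channel [raw_image()] or matrix.
#' @param window odd window side (px).
#' @return Intensity matrix.
#' @export
median_smooth <- function(img, window = 5L) {
  cpp_median_filter(as_px_matrix(img), as.integer(window))
}

#' Contrast-limited adaptive histogram equalization
#'
#' Tile-wise equalization: each tile's 256-bin histogram is clipped at
#' `clip_limit` times the uniform level (tile pixels / 256), the excess is
#' redistributed uniformly in a single pass, and the tile mapping is the
#' scaled midpoint CDF (center-of-bin rule, so a flat histogram -- and in
#' particular a constant tile -- maps to the identity).  Pixel values are
#' bilinearly interpolated between the
#' mappings of the four surrounding tile centers.
#'
#' @param img single-channel [raw_image()] or matrix.
#' @param clip_limit positive clip limit (1.0 clips at the uniform level).
#' @param grid tiles per image side.
#' @return Intensity matrix.
#' @export
clahe_equalize <- function(img, clip_limit = 1.0, grid = 8L) {
  g <- as_px_matrix(img)
  h <- nrow(g); w <- ncol(g)
  rb <- round(seq(0, h, length.out = grid + 1L))
  cb <- round(seq(0, w, length.out = grid + 1L))
  ctr_r <- (utils::head(rb, -1L) + 1 + utils::tail(rb, -1L)) / 2
  ctr_c <- (utils::head(cb, -1L) + 1 + utils::tail(cb, -1L)) / 2
  maps <- matrix(0, grid * grid, 256L)  # row = tile (i + (j-1)*grid)
  for (j in seq_len(grid)) {
    for (i in seq_len(grid)) {
      tile <- g[(rb[i] + 1L):rb[i + 1L], (cb[j] + 1L):cb[j + 1L]]
      n_t <- length(tile)
      hist <- tabulate(tile + 1L, 256L)
      if (sum(hist > 0) <= 1L) {
        # constant tile: equalization is degenerate, keep the identity
        maps[i + (j - 1L) * grid, ] <- 0:255
        next
      }
      clip <- clip_limit * n_t / 256
      excess <- sum(pmax(hist - clip, 0))
      h2 <- pmin(hist, clip) + excess / 256
      cdf <- cumsum(h2)
      # midpoint (center-of-bin) equalization: a flat histogram maps to
      # the identity
      map <- pmin(pmax(round_half_up(255 * (cdf - h2 / 2) / n_t), 0), 255)
      maps[i + (j - 1L) * grid, ] <- map
    }
  }
  interp_axis <- function(pos, centers) {
    grid_n <- length(centers)
    if (grid_n == 1L) {
      return(list(lo = rep(1L, length(pos)), hi = rep(1L, length(pos)),
                  w = rep(0, length(pos))))
    }
    lo <- findInterval(pos, centers)
    lo <- pmin(pmax(lo, 1L), grid_n - 1L)
    wgt <- (pos - centers[lo]) / (centers[lo + 1L] - centers[lo])
    wgt <- pmin(pmax(wgt, 0), 1)
    list(lo = lo, hi = lo + 1L, w = wgt)
  }
  ra <- interp_axis(seq_len(h), ctr_r)
  ca <- interp_axis(seq_len(w), ctr_c)
  v1 <- g + 1L
  lookup <- function(ti, tj) {
    tile_idx <- matrix(ti, h, w) + (matrix(tj, h, w, byrow = TRUE) - 1L) * grid
    matrix(maps[cbind(as.vector(tile_idx), as.vector(v1))], h, w)
  }
  wr <- matrix(ra$w, h, w)
  wc <- matrix(ca$w, h, w, byrow = TRUE)
  out <- (1 - wr) * (1 - wc) * lookup(ra$lo, ca$lo) +
    (1 - wr) * wc * lookup(ra$lo, ca$hi) +
    wr * (1 - wc) * lookup(ra$hi, ca$lo) +
    wr * wc * lookup(ra$hi, ca$hi)
  quantize8(out)
}

# brightness bias then contrast scaling (or swapped), clipping after each step
bias_contrast <- function(g, bias, scale, brightness_first = TRUE) {
  if (brightness_first) {
    quantize8(clip8(g + bias) * scale)
  } else {
    quantize8(clip8(g * scale) + bias)
  }
}

#' Five-stage image enhancement
#'
#' Applies, in order: Gaussian smoothing, the 3x3 sharpening stencil,
#' median filtering, CLAHE, and brightness/contrast adjustment
#' (`(v + bias) * scale`, clipped after each step).
#'
#' @param gray single-channel [raw_image()] or matrix.
#' @param params an [enhance_params()].
#' @return Intensity matrix of the same shape.
#' @export
enhance <- function(gray, params = enhance_params()) {
  g <- as_px_matrix(gray)
  g <- gaussian_smooth(g, params$gaussian_kernel, params$gaussian_sigma)
  g <- sharpen_filter(g)
  g <- median_smooth(g, params$median_window)
  g <- clahe_equalize(g, params$clahe_clip_limit, params$clahe_grid)
  bias_contrast(g, params$brightness_bias, params$contrast_scale,
                params$brightness_first)
}

#' Full preprocessing chain
#'
#' Composes the capture-to-working-image chain: FOV estimation, square
#' crop, grayscale conversion, FOV masking, in-mask min-max normalization,
#' tracked resize to `params$resize_side`, enhancement, and a final
#' re-application of the mask (outside pixels forced to zero).
#'
#' @param raw a [raw_image()].
#' @param calib an [optical_calibration()] for the raw capture.
#' @param params an [enhance_params()].
#' @param fov optional [fov_geometry()] to use instead of [estimate_fov()].
#' @return A [processed_image()].
#' @export
preprocess <- function(raw, calib = optical_calibration(),
                       params = enhance_params(), fov = NULL) {
  if (!inherits(raw, "raw_image")) raw <- raw_image(raw)
  if (is.null(fov)) fov <- estimate_fov(raw)
  cropped <- crop_square(raw, fov)
  origin <- attr(cropped, "origin")
  gray <- to_gray(cropped)
  g <- as_px_matrix(gray)
  side <- nrow(g)
  # FOV geometry in the cropped frame
  cr <- fov$center_row - origin[1L] + 1
  cc <- fov$center_col - origin[2L] + 1
  dr <- (seq_len(side) - cr)^2
  dc <- (seq_len(side) - cc)^2
  mask <- outer(dr, dc, `+`) <= fov$radius^2
  g[!mask] <- 0L
  g <- normalize_in_mask(g, mask)
  rs <- resize_tracked(g, mask, calib, params$resize_side)
  out <- enhance(rs$image, params)
  out[!rs$mask] <- 0L
  processed_image(out, rs$mask, rs$scale,
                  provenance = c("crop", "grayscale", "fov_mask",
                                 "normalize", "resize", "enhance"),
                  crop_origin = origin)
}
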