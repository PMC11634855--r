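# shared fixtures and independent oracles, built in code at test time

# uniform disk of intensity fg on background bg
make_disk_image <- function(h, w, cy, cx, r, fg = 200L, bg = 5L) {
  d2 <- outer((seq_len(h) - cy)^2, (seq_len(w) - cx)^2, `+`)
  m <- matrix(bg, h, w)
  m[d2 <= r^2] <- fg
  storage.mode(m) <- "integer"
  m
}

# darker anti-aliased disk with a paler interior on a bright background
# (cell-like); intensities chosen so Canny fires on the outer boundary
make_cell_image <- function(h, w, cy, cx, r, ring = TRUE) {
  d <- sqrt(outer((seq_len(h) - cy)^2, (seq_len(w) - cx)^2, `+`))
  alpha <- pmin(pmax(r + 0.5 - d, 0), 1)
  inner <- if (ring) {
    120 + 35 * pmin(pmax(0.55 * r + 0.5 - d, 0), 1)
  } else 120
  img <- 180 * (1 - alpha) + inner * alpha
  m <- floor(img + 0.5)
  storage.mode(m) <- "integer"
  m
}

# 1 px rasterized circle as a boolean edge map
rasterize_circle_edges <- function(h, w, cy, cx, r) {
  th <- seq(0, 2 * pi, length.out = 1441L)[-1441L]
  m <- matrix(FALSE, h, w)
  ry <- round(cy + r * sin(th)); rx <- round(cx + r * cos(th))
  ok <- ry >= 1 & ry <= h & rx >= 1 & rx <= w
  m[cbind(ry[ok], rx[ok])] <- TRUE
  m
}

# exhaustive minimal-enclosing-circle oracle: tries every pair and triple
# of hull points and keeps the smallest circle containing all points
mec_oracle <- function(pts) {
  pts <- as.matrix(pts)
  hull <- grDevices::chull(pts[, 2L], pts[, 1L])
  hp <- pts[hull, , drop = FALSE]
  n <- nrow(hp)
  contains_all <- function(ctr, r) {
    all(sqrt((hp[, 1L] - ctr[1L])^2 + (hp[, 2L] - ctr[2L])^2) <= r + 1e-7)
  }
  best <- NULL
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ctr <- (hp[i, ] + hp[j, ]) / 2
    r <- sqrt(sum((hp[i, ] - ctr)^2))
    if (contains_all(ctr, r) && (is.null(best) || r < best$radius)) {
      best <- list(center = ctr, radius = r)
    }
  }
  if (n >= 3L) for (i in seq_len(n - 2L)) for (j in (i + 1L):(n - 1L)) {
    for (k in (j + 1L):n) {
      a <- hp[i, ]; b <- hp[j, ]; c <- hp[k, ]
      d <- 2 * (a[1L] * (b[2L] - c[2L]) + b[1L] * (c[2L] - a[2L]) +
                  c[1L] * (a[2L] - b[2L]))
      if (abs(d) < 1e-9) next
      ux <- (sum(a^2) * (b[2L] - c[2L]) + sum(b^2) * (c[2L] - a[2L]) +
               sum(c^2) * (a[2L] - b[2L])) / d
      uy <- (sum(a^2) * (c[1L] - b[1L]) + sum(b^2) * (a[1L] - c[1L]) +
               sum(c^2) * (b[1L] - a[1L])) / d
      ctr <- c(ux, uy)
      r <- sqrt(sum((a - ctr)^2))
      if (contains_all(ctr, r) && (is.null(best) || r < best$radius)) {
        best <- list(center = ctr, radius = r)
      }
    }
  }
  best
}

# map ground-truth circles from the raw frame into the processed frame
truth_in_processed_frame <- function(truth, img, fov, proc) {
  org <- proc$crop_origin
  f <- proc$scale$resize_factor
  tt <- truth$cells
  tt$center_row <- (tt$center_row - org[1L] + 1) * f
  tt$center_col <- (tt$center_col - org[2L] + 1) * f
  tt$radius_px <- tt$radius_px * f
  tt
}

# compact study conditions for property sweeps: same optics and cell sizes,
# smaller frame so many seeds stay affordable
sweep_params <- function(...) {
  synth_params(raw_side = 1200L, n_cells_range = c(3L, 6L),
               n_dirt_range = c(0L, 0L), noise_sigma = 0, ...)
}

single_precision_val <- function(m) smearcount:::single_precision(m)
single_recall_val <- function(m) smearcount:::single_recall(m)

# run the complete pipeline on one scene; returns detections and truth in
# the processed frame
run_pipeline <- function(truth, calib = optical_calibration()) {
  img <- render_scene(truth)
  fov <- estimate_fov(img)
  proc <- preprocess(img, calib, fov = fov)
  res <- count_cells(proc)
  list(result = res, proc = proc,
       truth_px = truth_in_processed_frame(truth, img, fov, proc))
}
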