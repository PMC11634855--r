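#' Parameters of the synthetic blood-smear generator
#'
#' Defaults emulate the reference capture conditions: a 3000 px raw frame
#' at 26.3 px/um with a bright circular field of view (90% of the
#' half-side) on a dark surround, 15-45 ring-profile erythrocytes of
#' 2.8-4.2 um radius with central pallor, cosine vignetting, Gaussian
#' sensor noise and a few sub-cell-size dirt speckles.
#'
#' @param raw_side raw frame side (px).
#' @param px_per_um raw pixel resolution (px/um).
#' @param fov_radius_frac FOV radius as a fraction of the half-side, (0, 1].
#' @param n_cells_range inclusive `(min, max)` cell count.
#' @param cell_radius_range_um cell radius range (um); kept strictly inside
#'   the 2.5-5 um detection gate so radius gating is not limiting.
#' @param min_center_separation_um minimum cell center separation (um);
#'   must exceed twice the maximum cell radius (no overlap).
#' @param ring_contrast intensity drop of the cell rim below the local
#'   background (8-bit units).
#' @param center_pallor intensity of the cell interior above the rim.
#' @param vignette_strength fractional illumination loss at the FOV rim.
#' @param noise_sigma additive Gaussian noise standard deviation.
#' @param n_dirt_range inclusive `(min, max)` dirt speckle count.
#' @param dirt_radius_range_um dirt radius range (um); below the minimum
#'   cell radius.
#' @return An object of class `synth_params`.
#' @export
synth_params <- function(raw_side = 3000L, px_per_um = 26.3,
                         fov_radius_frac = 0.9,
                         n_cells_range = c(15L, 45L),
                         cell_radius_range_um = c(2.8, 4.2),
                         min_center_separation_um = 9.0,
                         ring_contrast = 60, center_pallor = 35,
                         vignette_strength = 0.25, noise_sigma = 5,
                         n_dirt_range = c(0L, 3L),
                         dirt_radius_range_um = c(0.5, 1.8)) {
  if (raw_side < 64L || px_per_um <= 0) {
    sc_stop("value_error", "invalid frame geometry")
  }
  if (fov_radius_frac <= 0 || fov_radius_frac > 1) {
    sc_stop("value_error", "fov_radius_frac must be in (0, 1]")
  }
  rng_ok <- function(r) length(r) == 2L && r[1L] <= r[2L] && all(r >= 0)
  if (!rng_ok(n_cells_range) || !rng_ok(cell_radius_range_um) ||
      !rng_ok(n_dirt_range) || !rng_ok(dirt_radius_range_um) ||
      cell_radius_range_um[1L] <= 0) {
    sc_stop("value_error", "invalid parameter range")
  }
  if (min_center_separation_um <= 2 * cell_radius_range_um[2L]) {
    sc_stop("value_error",
            "min separation must exceed twice the max cell radius")
  }
  structure(list(raw_side = as.integer(raw_side), px_per_um = px_per_um,
                 fov_radius_frac = fov_radius_frac,
                 n_cells_range = as.integer(n_cells_range),
                 cell_radius_range_um = cell_radius_range_um,
                 min_center_separation_um = min_center_separation_um,
                 ring_contrast = ring_contrast,
                 center_pallor = center_pallor,
                 vignette_strength = vignette_strength,
                 noise_sigma = noise_sigma,
                 n_dirt_range = as.integer(n_dirt_range),
                 dirt_radius_range_um = dirt_radius_range_um),
            class = "synth_params")
}

# uniform point in a disk of radius R (um offsets from the FOV center)
runif_disk <- function(R) {
  th <- runif(1L, 0, 2 * pi)
  rr <- R * sqrt(runif(1L))
  c(rr * cos(th), rr * sin(th))
}

#' Generate a synthetic scene with exact ground truth
#'
#' Cell layout is drawn in micrometre coordinates relative to the FOV
#' center (so the same seed yields the same physical scene at any
#' calibration): the cell count is uniform in `n_cells_range`, radii
#' uniform in `cell_radius_range_um`, and centers are rejection-sampled
#' inside the FOV with margin at least one cell radius from the rim and
#' pairwise separation at least `min_center_separation_um`.  Dirt speckles
#' are placed anywhere inside the FOV without separation constraints.
#'
#' @param params a [synth_params()].
#' @param seed integer seed; the scene is fully determined by it.
#' @return An object of class `scene_truth`: `list(cells, dirt, fov, seed,
#'   params)`; `cells` and `dirt` are data frames in raw-image pixels with
#'   columns `center_row`, `center_col`, `radius_px`, `radius_um`.
#' @export
generate_scene <- function(params = synth_params(), seed = 1L) {
  fov_r_px <- params$fov_radius_frac * params$raw_side / 2
  fov_ctr <- (params$raw_side + 1) / 2
  R_um <- fov_r_px / params$px_per_um
  sep <- params$min_center_separation_um
  with_seed(seed, {
    n_cells <- sample_int_range(params$n_cells_range)
    # packing bound: disjoint disks of radius sep/2 around each center must
    # fit in a disk of radius R + sep/2
    if (n_cells * (sep / 2)^2 > (R_um + sep / 2)^2) {
      sc_stop("placement_error", sprintf(
        "%d cells at %.3g um separation cannot fit in a %.3g um FOV",
        n_cells, sep, R_um))
    }
    radii_um <- runif(n_cells, params$cell_radius_range_um[1L],
                      params$cell_radius_range_um[2L])
    pos <- matrix(0, n_cells, 2L)
    if (n_cells > 0L) for (i in seq_len(n_cells)) {
      placed <- FALSE
      for (attempt in seq_len(10000L)) {
        p <- runif_disk(max(R_um - 2 * radii_um[i], 0))
        if (i == 1L ||
            all((pos[seq_len(i - 1L), 1L] - p[1L])^2 +
                  (pos[seq_len(i - 1L), 2L] - p[2L])^2 >= sep^2)) {
          pos[i, ] <- p
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        sc_stop("placement_error", sprintf(
          "could not place cell %d of %d after 10000 attempts", i, n_cells))
      }
    }
    n_dirt <- sample_int_range(params$n_dirt_range)
    dirt_um <- if (n_dirt > 0L) {
      runif(n_dirt, params$dirt_radius_range_um[1L],
            params$dirt_radius_range_um[2L])
    } else numeric(0)
    dirt_pos <- t(vapply(seq_len(n_dirt),
                         function(i) runif_disk(max(R_um - dirt_um[i], 0)),
                         numeric(2L)))
    if (n_dirt == 0L) dirt_pos <- matrix(0, 0L, 2L)
    cells <- data.frame(
      center_row = fov_ctr + pos[, 1L] * params$px_per_um,
      center_col = fov_ctr + pos[, 2L] * params$px_per_um,
      radius_px = radii_um * params$px_per_um,
      radius_um = radii_um
    )
    dirt <- data.frame(
      center_row = fov_ctr + dirt_pos[, 1L] * params$px_per_um,
      center_col = fov_ctr + dirt_pos[, 2L] * params$px_per_um,
      radius_px = dirt_um * params$px_per_um,
      radius_um = dirt_um
    )
    structure(list(cells = cells, dirt = dirt,
                   fov = fov_geometry(fov_ctr, fov_ctr, fov_r_px),
                   seed = as.integer(seed), params = params),
              class = "scene_truth")
  })
}

# closed-form vignetted background intensity at radial distance rho (px)
vignette_profile <- function(rho, fov_radius, strength, base = 190) {
  base * (1 - strength * (1 - cos(pi / 2 * pmin(rho / fov_radius, 1))))
}

#' Render a synthetic scene to an RGB capture
#'
#' Background: dark surround (intensity 8) with a bright FOV disk (base
#' 190) darkened radially by a cosine vignette.  Each cell is an
#' anti-aliased ring: rim at local background minus `ring_contrast`, with
#' the interior (central pallor, inside 0.55 of the radius) brighter than
#' the rim by `center_pallor`.  Dirt speckles are dark blobs (local
#' background minus 90).  Gaussian noise with `noise_sigma` is added under
#' a sub-seed derived from the scene seed, and the single channel is
#' replicated to RGB with a slight warm tint (R +6, B -6).
#'
#' @param truth a [generate_scene()] result.
#' @return A 3-channel [raw_image()].
#' @export
render_scene <- function(truth) {
  p <- truth$params
  n <- p$raw_side
  fov <- truth$fov
  img <- cpp_render_background(n, n, fov$center_row, fov$center_col,
                               fov$radius, p$vignette_strength, 190, 8)

  draw_disk <- function(img, cy, cx, r, value_fun) {
    lo_r <- max(floor(cy - r - 3), 1L); hi_r <- min(ceiling(cy + r + 3), n)
    lo_c <- max(floor(cx - r - 3), 1L); hi_c <- min(ceiling(cx + r + 3), n)
    drow <- (lo_r:hi_r - cy)^2
    dcol <- (lo_c:hi_c - cx)^2
    d <- sqrt(outer(drow, dcol, `+`))
    alpha <- pmin(pmax(r + 0.5 - d, 0), 1)
    patch <- img[lo_r:hi_r, lo_c:hi_c]
    img[lo_r:hi_r, lo_c:hi_c] <- patch * (1 - alpha) + value_fun(d) * alpha
    img
  }
  for (i in seq_len(nrow(truth$cells))) {
    cy <- truth$cells$center_row[i]; cx <- truth$cells$center_col[i]
    r <- truth$cells$radius_px[i]
    local_bg <- vignette_profile(
      sqrt((cy - fov$center_row)^2 + (cx - fov$center_col)^2),
      fov$radius, p$vignette_strength)
    rim <- local_bg - p$ring_contrast
    r_in <- 0.55 * r
    img <- draw_disk(img, cy, cx, r, function(d) {
      # rim outside r_in, interior brighter by center_pallor, 1 px blend
      rim + p$center_pallor * pmin(pmax(r_in + 0.5 - d, 0), 1)
    })
  }
  for (i in seq_len(nrow(truth$dirt))) {
    cy <- truth$dirt$center_row[i]; cx <- truth$dirt$center_col[i]
    local_bg <- vignette_profile(
      sqrt((cy - fov$center_row)^2 + (cx - fov$center_col)^2),
      fov$radius, p$vignette_strength)
    img <- draw_disk(img, cy, cx, truth$dirt$radius_px[i],
                     function(d) local_bg - 90)
  }
  if (p$noise_sigma > 0) {
    noise_seed <- (truth$seed + 1000003L) %% 2147483647L
    img <- img + with_seed(noise_seed,
                           matrix(rnorm(n * n, 0, p$noise_sigma), n, n))
  }
  gi <- quantize8(img)
  out <- array(0L, dim = c(n, n, 3L))
  out[, , 1L] <- pmin(gi + 6L, 255L)
  out[, , 2L] <- gi
  out[, , 3L] <- pmax(gi - 6L, 0L)
  raw_image(out)
}

quantize8_array <- function(a) {
  a <- round_half_up(clip8(a))
  storage.mode(a) <- "integer"
  a
}

#' Write a synthetic dataset to disk
#'
#' Renders `n_images` scenes (per-image seeds `seed + 1 .. seed + n`) and
#' writes one PNG and one ground-truth CSV per image plus a `manifest.json`
#' recording parameters and seeds.  Re-running with the same arguments
#' reproduces the files byte for byte.
#'
#' @param n_images number of images, >= 1.
#' @param params a [synth_params()].
#' @param seed base integer seed.
#' @param dir output directory (created if missing).
#' @return Invisibly, a data frame with columns `image_id`, `image_path`,
#'   `truth_path`, `seed`, `n_cells`.
#' @export
generate_dataset <- function(n_images, params = synth_params(), seed = 42L,
                             dir) {
  if (n_images < 1L) sc_stop("value_error", "n_images must be >= 1")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    id <- sprintf("img_%03d", i)
    truth <- generate_scene(params, seed + i)
    img <- render_scene(truth)
    img_path <- file.path(dir, paste0(id, ".png"))
    truth_path <- file.path(dir, paste0(id, "_truth.csv"))
    png::writePNG(img$pixels / 255, img_path)
    write_truth_csv(truth, id, truth_path)
    rows[[i]] <- data.frame(image_id = id, image_path = img_path,
                            truth_path = truth_path, seed = seed + i,
                            n_cells = nrow(truth$cells))
  }
  index <- do.call(rbind, rows)
  manifest <- list(n_images = n_images, base_seed = seed,
                   params = unclass(params),
                   images = index[, c("image_id", "seed", "n_cells")])
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(index)
}

#' Write scene ground truth as CSV
#'
#' Columns: `image_id`, `center_row`, `center_col`, `radius_px`,
#' `radius_um`, `kind` (`cell` or `dirt`); coordinates in raw-image pixels.
#'
#' @param truth a [generate_scene()] result.
#' @param image_id identifier recorded in the file.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_csv <- function(truth, image_id, path) {
  tab <- rbind(
    cbind(truth$cells, kind = rep("cell", nrow(truth$cells))),
    cbind(truth$dirt, kind = rep("dirt", nrow(truth$dirt)))
  )
  tab <- cbind(image_id = rep(image_id, nrow(tab)), tab)
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Read a ground-truth or detection circle CSV
#'
#' @param path CSV path.
#' @param kind optional filter on the `kind` column (e.g. `"cell"`).
#' @return A circle data frame.
#' @export
read_circles_csv <- function(path, kind = NULL) {
  if (!file.exists(path)) {
    sc_stop("io_error", paste0("file not found: ", path))
  }
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(kind) && "kind" %in% names(tab)) {
    tab <- tab[tab$kind %in% kind, , drop = FALSE]
    rownames(tab) <- NULL
  }
  tab
}
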