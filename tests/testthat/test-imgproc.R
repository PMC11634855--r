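test_that("FOV estimation recovers synthetic disks and matches the exhaustive oracle", {
  img <- make_disk_image(400L, 400L, 200, 200, 150)
  fov <- estimate_fov(raw_image(img))
  expect_lt(abs(fov$center_row - 200), 2)
  expect_lt(abs(fov$center_col - 200), 2)
  expect_lt(abs(fov$radius - 150), 3)

  # translation equivariance
  img2 <- make_disk_image(400L, 400L, 150, 250, 140)
  fov2 <- estimate_fov(raw_image(img2))
  expect_lt(abs(fov2$center_row - 150), 2)
  expect_lt(abs(fov2$center_col - 250), 2)

  # against the exhaustive minimal-enclosing-circle oracle on the
  # thresholded pixel set of an irregular blob
  blob <- make_disk_image(200L, 200L, 90, 100, 50)
  blob[30:60, 120:160] <- 200L  # protrusion
  fov3 <- estimate_fov(raw_image(blob))
  pts <- which(blob > otsu_threshold(blob), arr.ind = TRUE)
  oracle <- mec_oracle(pts)
  expect_lt(abs(fov3$center_row - oracle$center[1L]), 1.5)
  expect_lt(abs(fov3$center_col - oracle$center[2L]), 1.5)
  expect_lt(abs(fov3$radius - oracle$radius), 1.5)
})

test_that("FOV estimation fails cleanly on dark or constant captures", {
  dark <- matrix(0L, 64L, 64L)
  expect_error(estimate_fov(raw_image(dark)), class = "no_fov_error")
  tiny <- matrix(0L, 128L, 128L)
  tiny[64:66, 64:66] <- 200L  # < 1% of pixels
  expect_error(estimate_fov(raw_image(tiny)), class = "no_fov_error")
})

test_that("minimal enclosing circle agrees with the exhaustive oracle on random point sets", {
  set.seed(11)
  for (rep in 1:8) {
    pts <- cbind(runif(40, 0, 100), runif(40, 0, 100))
    got <- min_enclosing_circle(pts)
    want <- mec_oracle(pts)
    expect_equal(got$radius, want$radius, tolerance = 1e-6)
    expect_equal(got$center, unname(want$center), tolerance = 1e-5)
  }
})

test_that("square crop is centered on the FOV and clamped at image borders", {
  img <- raw_image(make_disk_image(400L, 400L, 200, 200, 150))
  cr <- crop_square(img, fov_geometry(201, 201, 150))
  expect_equal(dim(cr$pixels), c(300L, 300L))
  expect_equal(attr(cr, "origin"), c(51L, 51L))

  # clamp near the corner
  cr2 <- crop_square(img, fov_geometry(10, 10, 150, NULL))
  expect_equal(dim(cr2$pixels), c(300L, 300L))
  expect_equal(attr(cr2, "origin"), c(1L, 1L))

  # FOV larger than the frame: whole image
  cr3 <- crop_square(img, fov_geometry(200, 200, 500, NULL))
  expect_equal(dim(cr3$pixels), c(400L, 400L))
})

test_that("grayscale conversion uses BT.601 luma with half-up rounding", {
  px <- array(0L, dim = c(32L, 32L, 3L))
  px[1, 1, ] <- c(255L, 255L, 255L)
  px[1, 2, ] <- c(100L, 100L, 100L)
  px[1, 3, ] <- c(255L, 0L, 0L)   # 0.299*255 = 76.245
  px[1, 4, ] <- c(0L, 255L, 0L)   # 0.587*255 = 149.685
  g <- to_gray(raw_image(px))
  expect_equal(g$pixels[1, 1:4], c(255L, 100L, 76L, 150L))
  # 1-channel input is a fixed point
  expect_identical(to_gray(g)$pixels, g$pixels)
})

test_that("in-mask normalization hits the {0, 255} endpoints and zeroes the outside", {
  g <- matrix(200L, 8L, 8L)
  mask <- matrix(FALSE, 8L, 8L)
  mask[1, 1:3] <- TRUE
  g[1, 1:3] <- c(50L, 100L, 150L)
  out <- normalize_in_mask(g, mask)
  expect_equal(out[1, 1:3], c(0L, 128L, 255L))  # 127.5 rounds half-up
  expect_true(all(out[!mask] == 0L))

  # already full range is unchanged
  g2 <- matrix(0L, 8L, 8L); g2[1, 2] <- 255L
  out2 <- normalize_in_mask(g2, matrix(TRUE, 8L, 8L))
  expect_identical(sort(unique(as.vector(out2))), c(0L, 255L))

  # constant FOV is a degenerate capture
  expect_error(normalize_in_mask(matrix(10L, 8L, 8L), matrix(TRUE, 8L, 8L)),
               class = "degenerate_image_error")

  # range-1 input survives and maps onto the endpoints
  g3 <- matrix(10L, 8L, 8L); g3[2, 2] <- 11L
  out3 <- normalize_in_mask(g3, matrix(TRUE, 8L, 8L))
  expect_identical(sort(unique(as.vector(out3))), c(0L, 255L))
})

test_that("tracked resize box-averages, resamples the mask and keeps the scale exact", {
  # 2x2 box average of a checkerboard is a half-gray constant
  cb <- matrix(0L, 4L, 4L)
  cb[(row(cb) + col(cb)) %% 2L == 0L] <- 255L
  W <- smearcount:::box_weight_matrix(4L, 2L)
  avg <- as.matrix(W %*% cb %*% Matrix::t(W))
  expect_true(all(abs(avg - 127.5) < 1e-9))

  calib <- optical_calibration(26.3)
  big <- matrix(128L, 1002L, 1002L)
  rs <- resize_tracked(big, matrix(TRUE, 1002L, 1002L), calib, 501L)
  expect_equal(rs$scale$resize_factor, 0.5)
  expect_equal(rs$scale$effective_px_per_um, 13.15)
  expect_equal(dim(rs$image), c(501L, 501L))
  # scale bookkeeping: effective * input side == raw * target side
  expect_equal(rs$scale$effective_px_per_um * 1002,
               calib$px_per_um * 501, tolerance = 1e-12)

  # identity when sides match
  id <- resize_tracked(matrix(7L, 501L, 501L), matrix(TRUE, 501L, 501L),
                       calib, 501L)
  expect_identical(id$image, matrix(7L, 501L, 501L))
  expect_equal(id$scale$resize_factor, 1)

  # upscale warns
  expect_warning(
    resize_tracked(matrix(7L, 64L, 64L), matrix(TRUE, 64L, 64L), calib, 128L),
    "upscal")
})

test_that("mask resampling honours the half-coverage rule", {
  m <- matrix(FALSE, 128L, 128L)
  m[1:64, ] <- TRUE        # top half fully covered
  m[65, 1L] <- TRUE        # 1/4 coverage in the first lower 2x2 block
  m[65:66, 3:4] <- TRUE    # full coverage in the second block
  m[65, 5] <- TRUE         # exactly 1/2 coverage (block rows 65:66, col 5:6)
  m[66, 5] <- TRUE
  rs <- resize_tracked(matrix(100L, 128L, 128L), m, optical_calibration(1),
                       64L)
  expect_true(all(rs$mask[1:32, ]))
  expect_false(rs$mask[33L, 1L])   # 0.25 coverage
  expect_true(rs$mask[33L, 2L])    # 1.0 coverage
  expect_true(rs$mask[33L, 3L])    # 0.5 coverage passes the >= rule
  expect_false(any(rs$mask[34:64, ]))
})

test_that("sharpening matches a direct stencil evaluation and preserves constants", {
  m <- matrix(0L, 11L, 11L); m[6, 6] <- 10L
  s <- sharpen_filter(m)
  expect_equal(s[6, 6], 90L)  # 9 * 10
  rest <- s; rest[6, 6] <- 0L
  expect_true(all(rest == 0L))  # -10 at the 8 neighbours clips to 0

  # constant identity (stencil sums to 1), several levels
  for (v in c(0L, 1L, 100L, 255L)) {
    expect_identical(sharpen_filter(matrix(v, 16L, 16L)),
                     matrix(v, 16L, 16L))
  }

  # against a nested-loop convolution oracle with reflect-101 borders
  set.seed(5)
  a <- matrix(sample.int(256L, 64L, replace = TRUE) - 1L, 8L, 8L)
  ref <- matrix(0L, 8L, 8L)
  refl <- function(i, n) {
    if (i < 1L) 2L - i else if (i > n) 2L * n - i else i
  }
  for (y in 1:8) for (x in 1:8) {
    acc <- 0L
    for (dy in -1:1) for (dx in -1:1) {
      k <- if (dy == 0L && dx == 0L) 9L else -1L
      acc <- acc + k * a[refl(y + dy, 8L), refl(x + dx, 8L)]
    }
    ref[y, x] <- min(max(acc, 0L), 255L)
  }
  expect_identical(sharpen_filter(a), ref)
})

test_that("median filter matches a brute-force oracle with reflective borders", {
  set.seed(9)
  a <- matrix(sample.int(256L, 81L, replace = TRUE) - 1L, 9L, 9L)
  got <- median_smooth(a, 3L)
  refl <- function(i, n) if (i < 1L) 2L - i else if (i > n) 2L * n - i else i
  for (y in c(1L, 5L, 9L)) for (x in c(1L, 2L, 9L)) {
    vals <- integer(0)
    for (dy in -1:1) for (dx in -1:1) {
      vals <- c(vals, a[refl(y + dy, 9L), refl(x + dx, 9L)])
    }
    expect_identical(got[y, x], as.integer(median(vals)))
  }
})

test_that("Gaussian smoothing agrees with EBImage on interior pixels", {
  set.seed(3)
  a <- matrix(sample.int(256L, 400L, replace = TRUE) - 1L, 20L, 20L)
  sigma <- 1.1
  got <- gaussian_smooth(a, 5L, sigma)
  # independent route: EBImage filter2 with the same sampled kernel
  x <- -2:2
  k1 <- exp(-x^2 / (2 * sigma^2)); k1 <- k1 / sum(k1)
  k2 <- outer(k1, k1)
  ref <- EBImage::filter2(EBImage::Image(a / 255), k2, boundary = "replicate")
  ref <- floor(as.matrix(ref) * 255 + 0.5)
  # borders differ (replicate vs reflect-101); compare the interior
  expect_true(all(abs(got[3:18, 3:18] - ref[3:18, 3:18]) <= 1))
})

test_that("Otsu threshold binarizes like EBImage's implementation", {
  set.seed(1)
  g <- matrix(as.integer(pmin(pmax(round(
    c(rnorm(5000, 60, 10), rnorm(5000, 180, 15))), 0), 255)), 100L, 100L)
  mine <- otsu_threshold(g)
  eb <- EBImage::otsu(EBImage::Image(g / 255), range = c(0, 1), levels = 256L)
  expect_identical(g > mine, matrix(g / 255 > eb, 100L, 100L))
})

test_that("CLAHE leaves constant images unchanged and keeps tile mappings monotone", {
  for (v in c(0L, 77L, 200L, 255L)) {
    expect_identical(clahe_equalize(matrix(v, 100L, 100L)),
                     matrix(v, 100L, 100L))
  }
  set.seed(2)
  a <- matrix(as.integer(pmin(pmax(round(rnorm(10000, 120, 30)), 0), 255)),
              100L, 100L)
  out <- clahe_equalize(a, 2.0, 4L)
  expect_true(all(out >= 0L & out <= 255L))
  # with a single tile the mapping is global: monotone non-decreasing
  out1 <- clahe_equalize(a, 2.0, 1L)
  ord <- order(as.vector(a))
  expect_true(all(diff(as.vector(out1)[ord]) >= 0L))
})

test_that("the enhancement chain reproduces the constant-image arithmetic", {
  # all smoothing stages preserve constants; sharpening sums to 1; CLAHE is
  # the identity on constants; (100 + 7) * 1.02 = 109.14 -> 109
  out <- enhance(matrix(100L, 64L, 64L), enhance_params())
  expect_identical(out, matrix(109L, 64L, 64L))
  expect_identical(enhance(matrix(0L, 64L, 64L)),
                   matrix(as.integer(floor(7 * 1.02 + 0.5)), 64L, 64L))
})

test_that("preprocess yields the contracted shape, zero outside the mask, and is deterministic", {
  sp <- sweep_params()
  truth <- generate_scene(sp, 21L)
  img <- render_scene(truth)
  proc <- preprocess(img, optical_calibration(), enhance_params())
  expect_equal(dim(proc$pixels), c(501L, 501L))
  expect_identical(sum(proc$pixels[!proc$fov_mask]), 0L)
  expect_equal(proc$provenance,
               c("crop", "grayscale", "fov_mask", "normalize", "resize",
                 "enhance"))
  # deterministic: byte-identical re-run
  proc2 <- preprocess(img, optical_calibration(), enhance_params())
  expect_identical(proc$pixels, proc2$pixels)
  expect_identical(proc$fov_mask, proc2$fov_mask)
  # every ground-truth center lies inside the FOV mask
  fov <- estimate_fov(img)
  tt <- truth_in_processed_frame(truth, img, fov, proc)
  idx <- cbind(floor(tt$center_row + 0.5), floor(tt$center_col + 0.5))
  expect_true(all(proc$fov_mask[idx]))
})
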