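test_that("micrometre-to-pixel conversion follows the effective scale", {
  s1 <- scale_state(26.3, 1)
  expect_equal(um_to_px(2.5, s1), 65.75)
  expect_equal(um_to_px(0, s1), 0)
  s2 <- scale_state(26.3, 0.5)
  expect_equal(um_to_px(4.5, s2), 59.175)
})

test_that("pixel parameter conversion covers the micrometre interval conservatively", {
  s <- scale_state(26.3, 0.5)  # effective 13.15 px/um
  p <- to_px_params(detection_params_um(), s)
  expect_equal(p$min_radius_px, 32L)       # floor(32.875)
  expect_equal(p$max_radius_px, 66L)       # ceil(65.75)
  expect_equal(p$min_separation_px, 59)    # round(59.175)

  # a narrow but valid micrometre interval stays non-empty
  p2 <- to_px_params(detection_params_um(2.5, 2.6), scale_state(26.3, 1))
  expect_equal(p2$min_radius_px, 65L)
  expect_equal(p2$max_radius_px, 69L)

  # too-coarse image
  expect_error(to_px_params(detection_params_um(), scale_state(0.3, 1)),
               class = "scale_error")
})

test_that("brute-force Hough recovers rasterized circles exactly", {
  p <- detection_params_px(32L, 66L, 59, vote_threshold = 18)
  ed <- rasterize_circle_edges(201L, 201L, 101, 101, 40)
  bf <- hough_bruteforce(ed, p)
  top <- bf$candidates[1L, ]
  expect_lte(abs(top$center_row - 101), 1)
  expect_lte(abs(top$center_col - 101), 1)
  expect_lte(abs(top$radius_px - 40), 1)
  # accumulator dimensions and the winner's vote count match the raster
  expect_equal(dim(bf$accumulator), c(201L, 201L, 66L - 32L + 1L))
  expect_equal(top$votes, max(bf$accumulator))

  # blank image yields nothing
  blank <- matrix(FALSE, 64L, 64L)
  expect_equal(nrow(hough_bruteforce(blank, p)$candidates), 0L)

  # two disjoint circles are the top two candidates
  ed2 <- rasterize_circle_edges(256L, 256L, 70, 70, 35) |
    rasterize_circle_edges(256L, 256L, 180, 180, 50)
  top2 <- hough_bruteforce(ed2, p)$candidates[1:2, ]
  got <- top2[order(top2$center_row), ]
  expect_true(all(abs(got$center_row - c(70, 180)) <= 1))
  expect_true(all(abs(got$center_col - c(70, 180)) <= 1))
  expect_true(all(abs(got$radius_px - c(35, 50)) <= 1))
})

test_that("gradient Hough agrees with the exhaustive accumulator on small scenes", {
  # smooth-edged fixtures (as produced by the enhancement chain), <= 256 px,
  # up to 5 circles; each variant runs at its own vote operating point:
  # 18 center votes for gradient rays, half the minimum perimeter for the
  # exhaustive accumulator
  scenes <- list(
    list(size = c(201L, 201L), circ = data.frame(cy = 101, cx = 101, r = 40)),
    list(size = c(256L, 256L),
         circ = data.frame(cy = c(70, 180), cx = c(70, 170), r = c(35, 50))),
    list(size = c(256L, 256L),
         circ = data.frame(cy = c(60, 60, 190, 190, 128),
                           cx = c(60, 196, 60, 196, 128),
                           r = c(33, 36, 40, 44, 38)))
  )
  for (sc in scenes) {
    img <- matrix(180, sc$size[1L], sc$size[2L])
    for (i in seq_len(nrow(sc$circ))) {
      cell <- make_cell_image(sc$size[1L], sc$size[2L], sc$circ$cy[i],
                              sc$circ$cx[i], sc$circ$r[i])
      img <- pmin(img, cell)
    }
    img <- gaussian_smooth(smearcount:::quantize8(img), 5L)
    pg <- detection_params_px(32L, 66L, 59, vote_threshold = 18)
    grad <- suppress_min_distance(hough_gradient(img, pg), 59)
    ed <- canny_edges(img, 100, 50)
    pb <- detection_params_px(32L, 66L, 59,
                              vote_threshold = round(pi * 32))
    bf <- suppress_min_distance(hough_bruteforce(ed$edges, pb)$candidates, 59)
    expect_equal(nrow(grad), nrow(sc$circ))
    expect_equal(nrow(bf), nrow(sc$circ))
    og <- grad[order(grad$center_row, grad$center_col), ]
    ob <- bf[order(bf$center_row, bf$center_col), ]
    expect_true(all(abs(og$center_row - ob$center_row) <= 2))
    expect_true(all(abs(og$center_col - ob$center_col) <= 2))
    expect_true(all(abs(og$radius_px - ob$radius_px) <= 1))
  }
})

test_that("gradient Hough returns nothing on a blank image", {
  p <- detection_params_px(12L, 25L, 22, vote_threshold = 18)
  expect_equal(nrow(hough_gradient(matrix(128L, 128L, 128L), p)), 0L)
})

test_that("minimum-distance suppression is greedy by votes with deterministic ties", {
  two <- data.frame(center_row = c(10, 10), center_col = c(10, 13),
                    radius_px = c(5, 5), votes = c(100, 90))
  kept <- suppress_min_distance(two, 59)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$votes, 100)

  # boundary: distance equal to the separation is accepted
  apart <- data.frame(center_row = c(10, 10), center_col = c(10, 70),
                      radius_px = c(5, 5), votes = c(100, 90))
  expect_equal(nrow(suppress_min_distance(apart, 59)), 2L)
  expect_equal(nrow(suppress_min_distance(apart, 61)), 1L)

  # collinear chain: brute force over all acceptance orders confirms that
  # greedy-by-votes keeps the outer pair
  chain <- data.frame(center_row = c(10, 10, 10), center_col = c(0, 40, 80),
                      radius_px = c(5, 5, 5), votes = c(10, 9, 8))
  kept <- suppress_min_distance(chain, 59)
  expect_equal(sort(kept$center_col), c(0, 80))
  best <- NULL
  for (ord in list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                   c(3, 1, 2), c(3, 2, 1))) {
    acc <- integer(0)
    for (i in ord) {
      if (all(abs(chain$center_col[acc] - chain$center_col[i]) >= 59)) {
        acc <- c(acc, i)
      }
    }
    v <- sum(chain$votes[acc])
    if (is.null(best) || v > best$v) best <- list(v = v, acc = sort(acc))
  }
  expect_equal(sort(kept$center_col), chain$center_col[best$acc])

  # vote tie broken by smaller row then smaller col
  tie <- data.frame(center_row = c(20, 10), center_col = c(10, 10),
                    radius_px = c(5, 5), votes = c(50, 50))
  expect_equal(suppress_min_distance(tie, 59)$center_row, 10)
})

test_that("counting finds every clean synthetic cell and ignores dirt speckles", {
  sp <- synth_params(raw_side = 1500L, n_cells_range = c(8L, 8L),
                     noise_sigma = 0, n_dirt_range = c(0L, 0L))
  truth <- generate_scene(sp, 31L)
  out <- run_pipeline(truth)
  expect_equal(out$result$count, 8L)
  m <- match_circles(out$result$circles, out$truth_px, 3, out$proc$scale)
  expect_equal(m$n_tp, 8L)

  # same scene plus sub-cell-size dirt: count unchanged (radius gating)
  spd <- synth_params(raw_side = 1500L, n_cells_range = c(8L, 8L),
                      noise_sigma = 0, n_dirt_range = c(3L, 3L))
  truthd <- generate_scene(spd, 31L)
  expect_equal(nrow(truthd$dirt), 3L)
  expect_true(all(truthd$dirt$radius_um < 2.5))
  outd <- run_pipeline(truthd)
  expect_equal(outd$result$count, 8L)

  # blank FOV counts zero
  spb <- synth_params(raw_side = 1200L, n_cells_range = c(0L, 0L),
                      noise_sigma = 0, n_dirt_range = c(0L, 0L))
  blank <- run_pipeline(generate_scene(spb, 5L))
  expect_equal(blank$result$count, 0L)
})

test_that("detection respects separation, radius gating, monotonicity and determinism", {
  sp <- sweep_params()
  truth <- generate_scene(sp, 77L)
  img <- render_scene(truth)
  proc <- preprocess(img, optical_calibration())
  res <- count_cells(proc)
  # pairwise separations (exhaustive)
  if (res$count > 1L) {
    d <- as.matrix(dist(cbind(res$circles$center_row, res$circles$center_col)))
    expect_true(all(d[upper.tri(d)] >= res$params_px$min_separation_px))
  }
  # radius gate
  expect_true(all(res$circles$radius_px >= res$params_px$min_radius_px))
  expect_true(all(res$circles$radius_px <= res$params_px$max_radius_px))
  # determinism
  res2 <- count_cells(proc)
  expect_identical(res$circles, res2$circles)
  # raising the vote threshold never increases the candidate count
  pg <- res$params_px
  n_prev <- Inf
  for (thr in c(10, 18, 40, 80)) {
    pthr <- detection_params_px(pg$min_radius_px, pg$max_radius_px,
                                pg$min_separation_px, vote_threshold = thr)
    n_now <- nrow(hough_gradient(proc, pthr))
    expect_lte(n_now, n_prev)
    n_prev <- n_now
  }
})

test_that("the same physical scene gives the same count at two calibrations", {
  for (seed in c(3L, 14L)) {
    counts <- vapply(c(26.3, 13.15), function(cal) {
      sp <- synth_params(raw_side = if (cal == 26.3) 3000L else 1500L,
                         px_per_um = cal, n_cells_range = c(12L, 12L),
                         noise_sigma = 0, n_dirt_range = c(0L, 0L))
      truth <- generate_scene(sp, seed)
      run_pipeline(truth, optical_calibration(cal))$result$count
    }, numeric(1L))
    expect_equal(counts[1L], counts[2L])
    expect_equal(counts[1L], 12)
  }
})
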