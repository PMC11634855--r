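#' Convert a micrometre length to pixels
#'
#' @param length_um length in micrometres.
#' @param scale a [scale_state()]; the post-resize effective resolution is
#'   used, since detection runs on the resized working image.
#' @return Length in pixels (float).
#' @export
um_to_px <- function(length_um, scale) {
  length_um * scale$effective_px_per_um
}

#' Convert micrometre detection parameters to pixel parameters
#'
#' The radius gate is rounded conservatively (floor for the minimum, ceiling
#' for the maximum) so the full micrometre interval stays covered; the
#' separation is rounded half-up.
#'
#' @param p a [detection_params_um()].
#' @param scale a [scale_state()].
#' @param canny_high,canny_low,vote_threshold plumbing thresholds passed
#'   through to [detection_params_px()].
#' @param use_raw_scale convert with the raw (pre-resize) resolution instead
#'   of the effective one.
#' @return A [detection_params_px()].
#' @export
to_px_params <- function(p, scale, canny_high = 100,
                         canny_low = canny_high / 2, vote_threshold = 18,
                         use_raw_scale = FALSE) {
  ppu <- if (use_raw_scale) scale$raw_px_per_um else scale$effective_px_per_um
  min_r <- floor(p$min_radius_um * ppu)
  if (min_r < 1) {
    sc_stop("scale_error", sprintf(
      "minimum cell radius %.3g um is below 1 px at %.4g px/um",
      p$min_radius_um, ppu))
  }
  detection_params_px(
    min_radius_px = min_r,
    max_radius_px = ceiling(p$max_radius_um * ppu),
    min_separation_px = round_half_up(p$min_separation_um * ppu),
    canny_high = canny_high, canny_low = canny_low,
    vote_threshold = vote_threshold
  )
}

#' Canny edge detection
#'
#' Sobel gradients with reflect-101 borders, non-maximum suppression along
#' the quantized gradient direction, and double-threshold hysteresis
#' (8-connected).  Thresholds apply to the unnormalized Sobel L2 magnitude.
#'
#' @param img single-channel [raw_image()] or intensity matrix.
#' @param high,low hysteresis thresholds.
#' @return `list(edges, gx, gy, mag)` where `edges` is a logical matrix and
#'   `gx`/`gy` are the column/row Sobel derivatives.
#' @export
canny_edges <- function(img, high = 100, low = high / 2) {
  cpp_canny(as_px_matrix(img), high, low)
}

#' Exhaustive Hough circle accumulator (reference implementation)
#'
#' Every edge pixel votes for the rasterized perimeter (1 degree steps,
#' duplicate accumulator cells deduplicated per edge pixel) of every radius
#' in the gate.  Candidates are local maxima of the 3-D accumulator with at
#' least `vote_threshold` votes, sorted by votes descending (ties: smaller
#' row, then column).  Intended as the slow oracle the gradient-voting
#' detector is checked against; only practical on small images.
#'
#' @param edges logical edge matrix (e.g. from [canny_edges()]).
#' @param params_px a [detection_params_px()].
#' @return `list(candidates, accumulator)`: a circle data frame
#'   (`center_row`, `center_col`, `radius_px`, `votes`) and the full
#'   height x width x radii integer accumulator.
#' @export
hough_bruteforce <- function(edges, params_px) {
  res <- cpp_hough_bruteforce(edges, params_px$min_radius_px,
                              params_px$max_radius_px,
                              params_px$vote_threshold)
  res$candidates <- as.data.frame(res$candidates)
  res
}

#' Gradient-voting Hough circle detection
#'
#' Two-stage detection on the enhanced working image: Canny edges are
#' computed, each edge pixel votes along its gradient direction (both
#' senses) for centers at distances within the radius gate, and each
#' candidate center (accumulator local maximum with at least
#' `vote_threshold` votes) gets the mode of in-range edge distances as its
#' radius.
#'
#' @param processed a [processed_image()], single-channel [raw_image()] or
#'   intensity matrix.
#' @param params_px a [detection_params_px()].
#' @return Circle data frame (`center_row`, `center_col`, `radius_px`,
#'   `votes`) sorted by votes descending.
#' @export
hough_gradient <- function(processed, params_px) {
  g <- if (inherits(processed, "processed_image")) processed$pixels
       else as_px_matrix(processed)
  ed <- canny_edges(g, params_px$canny_high, params_px$canny_low)
  res <- cpp_hough_gradient(ed$edges, ed$gx, ed$gy,
                            params_px$min_radius_px, params_px$max_radius_px,
                            params_px$vote_threshold)
  as.data.frame(res$candidates)
}

#' Greedy minimum-distance suppression of circle candidates
#'
#' Candidates are visited in vote order (ties: smaller row, then column)
#' and accepted only if their center is at least `min_separation_px` away
#' from every already accepted center.
#'
#' @param candidates circle data frame sorted by votes descending.
#' @param min_separation_px minimum center separation (px).
#' @return The accepted subset, in acceptance order.
#' @export
suppress_min_distance <- function(candidates, min_separation_px) {
  n <- nrow(candidates)
  if (n == 0L) return(candidates)
  ord <- order(-candidates$votes, candidates$center_row,
               candidates$center_col)
  cand <- candidates[ord, , drop = FALSE]
  acc_r <- numeric(0); acc_c <- numeric(0)
  keep <- logical(n)
  for (i in seq_len(n)) {
    if (length(acc_r) == 0L ||
        all((acc_r - cand$center_row[i])^2 +
              (acc_c - cand$center_col[i])^2 >= min_separation_px^2)) {
      keep[i] <- TRUE
      acc_r <- c(acc_r, cand$center_row[i])
      acc_c <- c(acc_c, cand$center_col[i])
    }
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count cells in a processed image
#'
#' Full detection: micrometre parameters are converted to pixels with the
#' image's [scale_state()], the gradient Hough stage proposes candidates,
#' candidates whose centers fall outside the FOV mask are discarded, and
#' minimum-distance suppression yields the final set.
#'
#' @param processed a [processed_image()].
#' @param p a [detection_params_um()].
#' @param canny_high,canny_low,vote_threshold plumbing thresholds.
#' @return An object of class `cell_count_result`: `list(circles, count,
#'   params_px, scale)`.
#' @export
count_cells <- function(processed, p = detection_params_um(),
                        canny_high = 100, canny_low = canny_high / 2,
                        vote_threshold = 18) {
  params_px <- to_px_params(p, processed$scale, canny_high = canny_high,
                            canny_low = canny_low,
                            vote_threshold = vote_threshold)
  cand <- hough_gradient(processed, params_px)
  if (nrow(cand) > 0L) {
    inside <- processed$fov_mask[cbind(round_half_up(cand$center_row),
                                       round_half_up(cand$center_col))]
    cand <- cand[inside, , drop = FALSE]
  }
  circles <- suppress_min_distance(cand, params_px$min_separation_px)
  structure(list(circles = circles, count = nrow(circles),
                 params_px = params_px, scale = processed$scale),
            class = "cell_count_result")
}

#' @export
print.cell_count_result <- function(x, ...) {
  cat(sprintf("<cell_count_result: %d cells, radius gate [%d, %d] px, min separation %.4g px>\n",
              x$count, x$params_px$min_radius_px, x$params_px$max_radius_px,
              x$params_px$min_separation_px))
  invisible(x)
}
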