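#' Match detected circles to ground-truth circles
#'
#' Greedy one-to-one matching by ascending center distance: candidate pairs
#' within `tolerance_um` are accepted closest-first, skipping pairs whose
#' prediction or truth is already matched.  Unmatched predictions are false
#' positives, unmatched truths false negatives.
#'
#' @param pred,truth circle data frames with `center_row`, `center_col`
#'   (px in the same coordinate frame).
#' @param tolerance_um maximum center distance for a match (um).
#' @param scale a [scale_state()] used to convert pixel distances to um.
#' @return An object of class `match_result`: `list(pairs, n_tp, n_fp,
#'   n_fn, tolerance_um)` where `pairs` has columns `pred_idx`,
#'   `truth_idx`, `distance_um`.
#' @export
match_circles <- function(pred, truth, tolerance_um = 3, scale) {
  if (tolerance_um <= 0) sc_stop("value_error", "tolerance must be positive")
  np <- nrow(pred); nt <- nrow(truth)
  pairs <- data.frame(pred_idx = integer(0), truth_idx = integer(0),
                      distance_um = numeric(0))
  if (np > 0L && nt > 0L) {
    d_px <- sqrt(outer(pred$center_row, truth$center_row, `-`)^2 +
                   outer(pred$center_col, truth$center_col, `-`)^2)
    d_um <- d_px / scale$effective_px_per_um
    idx <- which(d_um <= tolerance_um, arr.ind = TRUE)
    if (nrow(idx) > 0L) {
      dd <- d_um[idx]
      ord <- order(dd, idx[, 1L], idx[, 2L])
      used_p <- logical(np); used_t <- logical(nt)
      for (k in ord) {
        i <- idx[k, 1L]; j <- idx[k, 2L]
        if (used_p[i] || used_t[j]) next
        used_p[i] <- TRUE; used_t[j] <- TRUE
        pairs <- rbind(pairs, data.frame(pred_idx = i, truth_idx = j,
                                         distance_um = d_um[i, j]))
      }
    }
  }
  n_tp <- nrow(pairs)
  structure(list(pairs = pairs, n_tp = n_tp, n_fp = np - n_tp,
                 n_fn = nt - n_tp, tolerance_um = tolerance_um),
            class = "match_result")
}

# per-image precision/recall with the zero-prediction convention:
# an image with no predictions has precision 1 if it also has no truths,
# else 0 (and analogously for recall with no truths)
single_precision <- function(m) {
  if (m$n_tp + m$n_fp == 0L) return(if (m$n_fn == 0L) 1 else 0)
  m$n_tp / (m$n_tp + m$n_fp)
}
single_recall <- function(m) {
  if (m$n_tp + m$n_fn == 0L) return(if (m$n_fp == 0L) 1 else 0)
  m$n_tp / (m$n_tp + m$n_fn)
}

#' Aggregate per-image precision and recall
#'
#' Per-image precision `tp/(tp+fp)` and recall `tp/(tp+fn)` are averaged
#' across images; spread is the sample standard deviation (n - 1
#' denominator), reported as 0 for a single image.
#'
#' @param per_image list of [match_circles()] results, one per image.
#' @return `list(precision_mean, precision_sd, recall_mean, recall_sd,
#'   per_image)` where `per_image` is a data frame of per-image values.
#' @export
prf_aggregate <- function(per_image) {
  n <- length(per_image)
  if (n == 0L) sc_stop("empty_eval_error", "no images to aggregate")
  p <- vapply(per_image, single_precision, numeric(1L))
  r <- vapply(per_image, single_recall, numeric(1L))
  if (n == 1L) message("single image: standard deviation reported as 0")
  list(precision_mean = mean(p),
       precision_sd = if (n > 1L) sd(p) else 0,
       recall_mean = mean(r),
       recall_sd = if (n > 1L) sd(r) else 0,
       per_image = data.frame(precision = p, recall = r))
}

#' Count-error metrics
#'
#' Mean absolute and mean squared error between algorithm and reference
#' per-image counts.
#'
#' @param pred_counts,true_counts equal-length integer vectors.
#' @return `list(mae, mse)`.
#' @export
count_error_metrics <- function(pred_counts, true_counts) {
  if (length(pred_counts) != length(true_counts)) {
    sc_stop("length_mismatch_error", "count vectors differ in length")
  }
  if (length(pred_counts) == 0L) {
    sc_stop("empty_eval_error", "no counts given")
  }
  d <- pred_counts - true_counts
  list(mae = mean(abs(d)), mse = mean(d^2))
}

#' Linear fit of algorithm counts against reference counts
#'
#' Ordinary least squares of `y` on `x`; the coefficient of determination
#' is `1 - SS_res / SS_tot`.
#'
#' @param x reference (manual or ground-truth) counts.
#' @param y algorithm counts.
#' @return `list(slope, intercept, r2)`.
#' @export
linear_r2 <- function(x, y) {
  if (length(x) < 3L) sc_stop("value_error", "need at least 3 points")
  if (length(unique(x)) == 1L) {
    sc_stop("degenerate_fit_error", "reference counts are constant")
  }
  fit <- lm(y ~ x)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  list(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
       r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else 0)
}

#' Evaluate detections against ground truth over a dataset
#'
#' Composes [match_circles()], [prf_aggregate()], [count_error_metrics()]
#' and [linear_r2()] into the standard validation report.  Detections and
#' truths must already share a coordinate frame (see [run_evaluate()] for
#' the raw-to-processed conversion).  Micro-averaged (pooled) precision and
#' recall are reported alongside the per-image means.
#'
#' @param pred_by_image,truth_by_image named lists of circle data frames;
#'   names are image ids and must coincide.
#' @param tolerance_um matching tolerance (um).
#' @param scale a single [scale_state()] or a named list of them per image.
#' @return An object of class `eval_report`.
#' @export
evaluate_dataset <- function(pred_by_image, truth_by_image, tolerance_um = 3,
                             scale) {
  ids <- names(pred_by_image)
  if (length(ids) == 0L) sc_stop("empty_eval_error", "no images to evaluate")
  if (!setequal(ids, names(truth_by_image))) {
    sc_stop("id_mismatch_error",
            "detection and truth image ids do not coincide")
  }
  ids <- sort(ids)
  matches <- lapply(ids, function(id) {
    sc <- if (inherits(scale, "scale_state")) scale else scale[[id]]
    match_circles(pred_by_image[[id]], truth_by_image[[id]], tolerance_um, sc)
  })
  prf <- prf_aggregate(matches)
  pred_counts <- vapply(pred_by_image[ids], nrow, integer(1L))
  true_counts <- vapply(truth_by_image[ids], nrow, integer(1L))
  err <- count_error_metrics(pred_counts, true_counts)
  fit <- if (length(ids) >= 3L && length(unique(true_counts)) > 1L) {
    linear_r2(as.numeric(true_counts), as.numeric(pred_counts))
  } else {
    # too few images (or constant reference counts) for a meaningful fit
    list(slope = NA_real_, intercept = NA_real_, r2 = NA_real_)
  }
  tp <- sum(vapply(matches, `[[`, integer(1L), "n_tp"))
  fp <- sum(vapply(matches, `[[`, integer(1L), "n_fp"))
  fn <- sum(vapply(matches, `[[`, integer(1L), "n_fn"))
  structure(list(
    precision_mean = prf$precision_mean, precision_sd = prf$precision_sd,
    recall_mean = prf$recall_mean, recall_sd = prf$recall_sd,
    micro_precision = if (tp + fp > 0) tp / (tp + fp) else 1,
    micro_recall = if (tp + fn > 0) tp / (tp + fn) else 1,
    mae = err$mae, mse = err$mse,
    slope = fit$slope, intercept = fit$intercept, r2 = fit$r2,
    n_images = length(ids),
    counts = data.frame(image_id = ids, true_count = as.integer(true_counts),
                        algo_count = as.integer(pred_counts))
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<eval_report over %d images>\n",
    "  precision %.4f +/- %.4f (micro %.4f)\n",
    "  recall    %.4f +/- %.4f (micro %.4f)\n",
    "  MAE %.4f  MSE %.4f\n",
    "  fit: y = %.4f x + %.4f, R^2 = %.5f\n"),
    x$n_images, x$precision_mean, x$precision_sd, x$micro_precision,
    x$recall_mean, x$recall_sd, x$micro_recall, x$mae, x$mse,
    x$slope, x$intercept, x$r2))
  invisible(x)
}

#' Write an evaluation report to JSON (and optionally a scatter plot)
#'
#' @param report an [evaluate_dataset()] result.
#' @param json_path output JSON path.
#' @param plot_path optional PNG path for the manual-vs-algorithm scatter.
#' @return `json_path`, invisibly.
#' @export
write_eval_report <- function(report, json_path, plot_path = NULL) {
  out <- unclass(report)
  out$counts <- NULL
  jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(plot_path)) {
    ok <- tryCatch({
      grDevices::png(plot_path, width = 600, height = 600)
      on.exit(grDevices::dev.off(), add = TRUE)
      plot(report$counts$true_count, report$counts$algo_count,
           xlab = "reference count", ylab = "algorithm count",
           main = if (is.finite(report$r2)) {
             sprintf("R^2 = %.5f", report$r2)
           } else "algorithm vs reference counts", pch = 19)
      if (is.finite(report$slope) && is.finite(report$intercept)) {
        graphics::abline(report$intercept, report$slope, col = "red")
      }
      TRUE
    }, error = function(e) {
      warning("could not write scatter plot: ", conditionMessage(e),
              call. = FALSE)
      FALSE
    })
    invisible(ok)
  }
  invisible(json_path)
}
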