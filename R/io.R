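#' Read an 8-bit image file
#'
#' PNG, JPEG and TIFF are supported (by file extension); values are
#' rescaled to `[0, 255]` integers.
#'
#' @param path image path.
#' @return A [raw_image()].
#' @export
read_image_file <- function(path) {
  if (!file.exists(path)) {
    sc_stop("io_error", paste0("file not found: ", path))
  }
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE)) {
        sc_stop("io_error", "the 'jpeg' package is required for JPEG input")
      }
      jpeg::readJPEG(path)
    },
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        sc_stop("io_error", "the 'tiff' package is required for TIFF input")
      }
      tiff::readTIFF(path)
    },
    sc_stop("io_error", paste0("unsupported image format: .", ext))
  )
  if (length(dim(arr)) == 3L && dim(arr)[3L] == 4L) {
    arr <- arr[, , 1:3]  # drop alpha
  }
  raw_image(quantize8_array(arr * 255))
}

#' Write a grayscale or RGB image as PNG
#'
#' @param img a [raw_image()], [processed_image()] or intensity matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(img, path) {
  px <- if (inherits(img, "processed_image")) img$pixels
        else if (inherits(img, "raw_image")) img$pixels
        else img
  png::writePNG(px / 255, path)
  invisible(path)
}

#' Write detections as CSV
#'
#' Columns: `image_id`, `center_row`, `center_col`, `radius_px`, `votes`
#' (processed-image pixel coordinates).
#'
#' @param detections named list of [count_cells()] results or circle data
#'   frames; names are image ids.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_detections_csv <- function(detections, path) {
  rows <- lapply(names(detections), function(id) {
    circ <- detections[[id]]
    if (inherits(circ, "cell_count_result")) circ <- circ$circles
    if (nrow(circ) == 0L) {
      return(NULL)
    }
    cbind(image_id = id,
          circ[, c("center_row", "center_col", "radius_px", "votes")])
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) {
    tab <- data.frame(image_id = character(0), center_row = numeric(0),
                      center_col = numeric(0), radius_px = numeric(0),
                      votes = numeric(0))
  }
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Draw detected circles on a processed image
#'
#' Circle perimeters are rasterized in red over the grayscale working
#' image, mirroring the usual "identified cells" overlay.
#'
#' @param processed a [processed_image()] or intensity matrix.
#' @param circles circle data frame.
#' @return An RGB array in `[0, 255]`.
#' @export
draw_overlay <- function(processed, circles) {
  g <- if (inherits(processed, "processed_image")) processed$pixels
       else as_px_matrix(processed)
  h <- nrow(g); w <- ncol(g)
  out <- array(0L, dim = c(h, w, 3L))
  out[, , 1L] <- g; out[, , 2L] <- g; out[, , 3L] <- g
  th <- seq(0, 2 * pi, length.out = 720L)
  for (i in seq_len(nrow(circles))) {
    ry <- round_half_up(circles$center_row[i] + circles$radius_px[i] * sin(th))
    rx <- round_half_up(circles$center_col[i] + circles$radius_px[i] * cos(th))
    ok <- ry >= 1 & ry <= h & rx >= 1 & rx <= w
    out[cbind(ry[ok], rx[ok], 1L)] <- 255L
    out[cbind(ry[ok], rx[ok], 2L)] <- 0L
    out[cbind(ry[ok], rx[ok], 3L)] <- 0L
  }
  out
}
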