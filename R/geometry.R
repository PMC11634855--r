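# exact minimal enclosing circle (Welzl's incremental algorithm with a
# deterministic pseudo-random insertion order); used by estimate_fov()

circle_from2 <- function(a, b) {
  c0 <- (a + b) / 2
  list(center = c0, radius = sqrt(sum((a - c0)^2)))
}

circle_from3 <- function(a, b, c) {
  # circumcircle; falls back to the largest 2-point circle when collinear
  d <- 2 * (a[1L] * (b[2L] - c[2L]) + b[1L] * (c[2L] - a[2L]) +
              c[1L] * (a[2L] - b[2L]))
  if (abs(d) < 1e-12) {
    cand <- list(circle_from2(a, b), circle_from2(a, c), circle_from2(b, c))
    ok <- vapply(cand, function(ci) {
      all(vapply(list(a, b, c), function(p) {
        sqrt(sum((p - ci$center)^2)) <= ci$radius + 1e-9
      }, logical(1L)))
    }, logical(1L))
    cand <- cand[ok]
    return(cand[[which.min(vapply(cand, `[[`, numeric(1L), "radius"))]])
  }
  ux <- (sum(a^2) * (b[2L] - c[2L]) + sum(b^2) * (c[2L] - a[2L]) +
           sum(c^2) * (a[2L] - b[2L])) / d
  uy <- (sum(a^2) * (c[1L] - b[1L]) + sum(b^2) * (a[1L] - c[1L]) +
           sum(c^2) * (b[1L] - a[1L])) / d
  ctr <- c(ux, uy)
  list(center = ctr, radius = sqrt(sum((a - ctr)^2)))
}

in_circle <- function(circ, p, tol = 1e-7) {
  sqrt(sum((p - circ$center)^2)) <= circ$radius + tol
}

#' Minimal enclosing circle of a point set
#'
#' Exact smallest circle containing all points, by Welzl's incremental
#' algorithm.  Insertion order is derandomized with a fixed multiplicative
#' hash so results are reproducible without touching the RNG stream.
#'
#' @param pts two-column matrix of (row, col) coordinates.
#' @return `list(center = c(row, col), radius = r)`.
#' @export
min_enclosing_circle <- function(pts) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  if (n == 0L) sc_stop("value_error", "no points given")
  if (n == 1L) return(list(center = as.numeric(pts[1L, ]), radius = 0))
  ord <- order((seq_len(n) * 2654435761) %% 4294967296)
  p <- pts[ord, , drop = FALSE]
  circ <- circle_from2(p[1L, ], p[2L, ])
  for (i in seq_len(n)[-(1:2)]) {
    pi_ <- p[i, ]
    if (in_circle(circ, pi_)) next
    # smallest circle of p[1..i-1] with pi_ on the boundary
    circ <- circle_from2(p[1L, ], pi_)
    for (j in seq_len(i - 1L)[-1L]) {
      pj <- p[j, ]
      if (in_circle(circ, pj)) next
      circ <- circle_from2(pj, pi_)
      for (k in seq_len(j - 1L)) {
        pk <- p[k, ]
        if (in_circle(circ, pk)) next
        circ <- circle_from3(pk, pj, pi_)
      }
    }
  }
  circ
}
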