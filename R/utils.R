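# shared numeric helpers; conventions used across every stage:
#   - (row, col) coordinates, 1-based, pixel centers at integer coordinates
#   - half-up rounding at every 8-bit re-quantization
#   - reflect-101 borders (edge pixel not duplicated) for all filters

round_half_up <- function(x) floor(x + 0.5)

clip8 <- function(x) pmin(pmax(x, 0), 255)

quantize8 <- function(x) {
  if (is.matrix(x) && is.double(x)) return(cpp_quantize8(x))
  m <- round_half_up(clip8(x))
  storage.mode(m) <- "integer"
  m
}

#' @noRd
reflect101_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  period <- 2L * (n - 1L)
  p <- (i - 1L) %% period
  p <- ifelse(p >= n, period - p, p)
  as.integer(p + 1L)
}

# error signalling: every condition carries class c(<specific>, "smearcount_error")
sc_stop <- function(class, msg, call. = sys.call(-1L)) {
  stop(structure(
    class = c(class, "smearcount_error", "error", "condition"),
    list(message = msg, call = call.)
  ))
}

# evaluate `code` under a fixed RNG seed without disturbing the caller's stream
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

# uniform integer in [lo, hi]; robust to lo == hi (unlike sample(lo:hi, 1))
sample_int_range <- function(range) {
  lo <- as.integer(range[1L]); hi <- as.integer(range[2L])
  lo + sample.int(hi - lo + 1L, 1L) - 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
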