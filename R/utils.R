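# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Restores the caller's `.Random.seed` afterwards so seeded operations do
#' not perturb the global RNG stream. A `NULL` seed evaluates the code
#' against the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic per-(participant, block, trial) stream derived from one
# master seed. Stays below 2^31 - 1; arithmetic kept within exact-double
# range (max intermediate ~2^36).
derive_seed <- function(master, ...) {
  parts <- c(master, ...)
  h <- 0
  for (p in parts) {
    h <- (h * 31 + (as.numeric(p) %% 2147483647)) %% 2147483647
  }
  as.integer(h)
}

deg2rad <- function(deg) deg * pi / 180

# Signed shortest angular difference to - from, in (-180, 180].
shortest_arc_delta <- function(from, to) {
  d <- (to - from) %% 360
  d[d > 180] <- d[d > 180] - 360
  d
}

# Minimum-image signed difference a - b on a circle of given period.
torus_delta <- function(a, b, period) {
  d <- (a - b) %% period
  d[d > period / 2] <- d[d > period / 2] - period
  d
}

# Wrap-aware Euclidean distance between points on the screen torus.
torus_dist <- function(x1, y1, x2, y2, screen_w, screen_h) {
  sqrt(torus_delta(x1, x2, screen_w)^2 + torus_delta(y1, y2, screen_h)^2)
}

# Unit-DC Hanning kernel (symmetric raised cosine, zero endpoints).
hanning_kernel <- function(n = 15L) {
  stopifnot(n >= 3L)
  k <- 0.5 - 0.5 * cos(2 * pi * seq(0L, n - 1L) / (n - 1L))
  k / sum(k)
}

# Moving-window smoothing at stride 1 with reflected edges.
smooth_hanning <- function(x, n = 15L) {
  if (length(x) < 2L) return(x)
  k <- hanning_kernel(n)
  half <- (n - 1L) %/% 2L
  pad <- min(half, length(x) - 1L)
  xp <- c(x[(pad + 1L):2L], x, x[(length(x) - 1L):(length(x) - pad)])
  if (pad < half) { # very short traces: extend by repetition
    xp <- c(rep(xp[1L], half - pad), xp, rep(xp[length(xp)], half - pad))
  }
  out <- stats::filter(xp, k, method = "convolution", sides = 2L)
  as.numeric(out[(half + 1L):(half + length(x))])
}

# Uniformly sample n ascending frames in [first, last] with consecutive
# gaps >= gap (classic gap-removal bijection; exact, no rejection).
sample_spaced_frames <- function(n, first, last, gap) {
  if (n == 0L) return(integer(0))
  m <- last - (n - 1L) * (gap - 1L)
  if (m - first + 1L < n) {
    stop("cannot place ", n, " events in [", first, ", ", last,
         "] with minimum gap ", gap, call. = FALSE)
  }
  y <- sort(sample(seq.int(first, m), n))
  as.integer(y + (seq_len(n) - 1L) * (gap - 1L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
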