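# Internal helpers shared across stages: padding, box sums, validation.

clamp01 <- function(x) pmin(pmax(x, 0), 1)

stop_if_not_image <- function(image) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("expected a numeric matrix (GrayImage)", call. = FALSE)
  if (any(!is.finite(image)))
    stop("image contains non-finite values", call. = FALSE)
  invisible(image)
}

stop_if_not_mask <- function(mask) {
  if (!is.matrix(mask)) stop("expected a matrix mask", call. = FALSE)
  v <- as.vector(mask)
  if (!all(v %in% c(0, 1))) stop("mask values must be strictly 0/1", call. = FALSE)
  invisible(mask)
}

check_odd_window <- function(window, shape) {
  if (length(window) != 1L || window < 3 || window %% 2 == 0)
    stop("window must be an odd integer >= 3, got ", window, call. = FALSE)
  if (window > min(shape))
    stop("window (", window, ") exceeds image extent ", min(shape), call. = FALSE)
  invisible(as.integer(window))
}

# Symmetric (mirror, edge-repeating) padding by `p` pixels on every side.
# The same border convention is used by every windowed stage of the pipeline.
pad_symmetric <- function(x, p) {
  if (p == 0L) return(x)
  h <- nrow(x); w <- ncol(x)
  if (p > h || p > w) stop("padding exceeds image size", call. = FALSE)
  ri <- c(p:1, 1:h, h:(h - p + 1L))
  ci <- c(p:1, 1:w, w:(w - p + 1L))
  x[ri, ci, drop = FALSE]
}

# Moving-window sum over a w x w window with symmetric padding, via a
# summed-area table. Exact for integer-valued inputs (counts stay < 2^53).
box_sum <- function(x, window) {
  p <- (window - 1L) %/% 2L
  h <- nrow(x); w <- ncol(x)
  xp <- pad_symmetric(x, p)
  s <- apply(xp, 2L, cumsum)
  s <- t(apply(s, 1L, cumsum))
  s0 <- matrix(0, nrow(xp) + 1L, ncol(xp) + 1L)
  s0[-1L, -1L] <- s
  n <- 2L * p + 1L
  s0[(1:h) + n, (1:w) + n, drop = FALSE] -
    s0[1:h, (1:w) + n, drop = FALSE] -
    s0[(1:h) + n, 1:w, drop = FALSE] +
    s0[1:h, 1:w, drop = FALSE]
}

box_mean <- function(x, window) box_sum(x, window) / (window * window)

# Shift a matrix by (dr, dc), exposing `fill` at the vacated border.
shift_matrix <- function(x, dr, dc, fill = 0) {
  h <- nrow(x); w <- ncol(x)
  out <- matrix(fill, h, w)
  rs <- max(1L, 1L + dr):min(h, h + dr)
  cs <- max(1L, 1L + dc):min(w, w + dc)
  out[rs, cs] <- x[rs - dr, cs - dc, drop = FALSE]
  out
}

# Evaluate an RNG-consuming expression under a given seed without disturbing
# the caller's random stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
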