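# Fixtures and independent brute-force oracles used across the suite.

random_image <- function(h, w = h) matrix(runif(h * w), h, w)

# Vertical step edge: 0 left of `at`, 1 from column `at` on.
step_edge_image <- function(h, w, at = w %/% 2) {
  img <- matrix(0, h, w)
  img[, at:w] <- 1
  img
}

checkerboard_image <- function(h, w = h, lo = 0.25, hi = 0.75) {
  idx <- outer(seq_len(h), seq_len(w), `+`)
  matrix(ifelse(idx %% 2 == 0, lo, hi), h, w)
}

disk_mask <- function(h, w, center, radius) {
  R <- matrix(seq_len(h), h, w)
  C <- matrix(seq_len(w), h, w, byrow = TRUE)
  matrix(as.integer((R - center[1])^2 + (C - center[2])^2 <= radius^2), h, w)
}

square_mask <- function(h, w, r0, c0, side) {
  m <- matrix(0L, h, w)
  m[r0:(r0 + side - 1), c0:(c0 + side - 1)] <- 1L
  m
}

# --- independent oracles ----------------------------------------------------

# Per-pixel windowed histogram entropy by direct tabulation; mirrors only the
# stated definition (256-level quantization, symmetric padding), not the
# implementation's summed-area-table path.
oracle_entropy <- function(image, window) {
  p <- (window - 1L) %/% 2L
  h <- nrow(image); w <- ncol(image)
  ri <- c(p:1, 1:h, h:(h - p + 1L))
  ci <- c(p:1, 1:w, w:(w - p + 1L))
  q <- matrix(as.integer(round(image * 255)), h, w)[ri, ci]
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    win <- q[i:(i + 2L * p), j:(j + 2L * p)]
    counts <- tabulate(as.vector(win) + 1L, 256L)
    pr <- counts / length(win)
    out[i, j] <- sum(ifelse(counts > 0L, -pr * log2(pr), 0))
  }
  out
}

# Occupied-box count by explicit double loop over the tiling.
oracle_box_count <- function(mask, r) {
  h <- nrow(mask); w <- ncol(mask)
  n <- 0L
  for (i in seq(1L, h, by = r)) for (j in seq(1L, w, by = r)) {
    if (any(mask[i:min(i + r - 1L, h), j:min(j + r - 1L, w)] == 1L))
      n <- n + 1L
  }
  n
}

# Connected components by breadth-first flood fill (slow, obviously correct).
oracle_label <- function(mask, connectivity = 8L) {
  h <- nrow(mask); w <- ncol(mask)
  offs <- if (connectivity == 8L)
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  lab <- matrix(0L, h, w)
  k <- 0L
  for (start in which(mask == 1L & lab == 0L)) {
    if (lab[start] != 0L) next
    k <- k + 1L
    queue <- start
    lab[start] <- k
    while (length(queue)) {
      cur <- queue[1L]; queue <- queue[-1L]
      ci <- (cur - 1L) %% h + 1L
      cj <- (cur - 1L) %/% h + 1L
      for (o in seq_len(nrow(offs))) {
        ni <- ci + offs[o, 1L]; nj <- cj + offs[o, 2L]
        if (ni >= 1L && ni <= h && nj >= 1L && nj <= w) {
          lin <- (nj - 1L) * h + ni
          if (mask[lin] == 1L && lab[lin] == 0L) {
            lab[lin] <- k
            queue <- c(queue, lin)
          }
        }
      }
    }
  }
  lab
}

single_disk_scene <- function(radius = 50, size = c(256L, 256L),
                              noise_sigma = 0, seed = 7L) {
  generate_scene(scene_spec(
    list(list(kind = "disk", center = round(size / 2), radius = radius,
              intensity = 0.7)),
    size = size, noise_sigma = noise_sigma, seed = seed))
}
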