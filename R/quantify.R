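# Box-counting quantification: occupied-box series, fractal dimension,
# region area and boundary-box perimeter.

#' Dyadic box-size ladder for a given image shape
#'
#' `r = 2^k` for `k = 1, ..., floor(log2(min(H, W))) - 1`.
#'
#' @param shape Integer vector `c(H, W)`.
#' @return Increasing integer vector of box side lengths.
#' @export
dyadic_box_sizes <- function(shape) {
  kmax <- floor(log2(min(shape))) - 1L
  if (kmax < 1L) stop("image too small for dyadic box sizes", call. = FALSE)
  as.integer(2^seq_len(kmax))
}

#' Occupied-box counts of a binary mask
#'
#' For each box side `r` the frame is tiled from the origin into an
#' axis-aligned grid of `r x r` boxes (ragged boxes at the right/bottom edges
#' included) and the number of boxes containing foreground is counted. With
#' `occupancy = "ge1"` (standard) a box counts when it holds at least one
#' foreground pixel; `"gt1"` requires strictly more than one.
#'
#' @param mask Integer 0/1 matrix, non-empty.
#' @param sizes Strictly increasing box side lengths (each >= 2).
#' @param occupancy `"ge1"` or `"gt1"`.
#' @return A `box_count_series`: data frame with columns `r` and `N`.
#' @export
box_counts <- function(mask, sizes, occupancy = c("ge1", "gt1")) {
  stop_if_not_mask(mask)
  occupancy <- match.arg(occupancy)
  if (sum(mask) == 0)
    stop("mask is empty: nothing to count; skip quantification", call. = FALSE)
  sizes <- as.integer(sizes)
  if (any(sizes < 2L) || any(diff(sizes) <= 0L))
    stop("sizes must be strictly increasing integers >= 2", call. = FALSE)
  fg <- which(mask == 1L, arr.ind = TRUE)
  N <- vapply(sizes, function(r) {
    br <- (fg[, 1L] - 1L) %/% r
    bc <- (fg[, 2L] - 1L) %/% r
    nb <- max(br) + 1L
    counts <- tabulate(br + bc * nb + 1L)
    if (occupancy == "ge1") sum(counts >= 1L) else sum(counts > 1L)
  }, integer(1L))
  structure(data.frame(r = sizes, N = N), class = c("box_count_series",
                                                    "data.frame"))
}

#' Fractal dimension from a box-count series
#'
#' Unweighted ordinary least-squares fit of `ln N` against `ln(1/r)`: the
#' slope is the box-counting fractal dimension. The intercept and the RMS of
#' the `ln N` residuals are attached as attributes.
#'
#' @param series A `box_count_series` (or data frame with columns `r`, `N`)
#'   of at least 3 pairs with all `N >= 1`.
#' @return The fitted dimension (numeric scalar) with attributes
#'   `"intercept"` and `"residual"`.
#' @export
fractal_dimension <- function(series) {
  if (nrow(series) < 3L)
    stop("need at least 3 (r, N) pairs to fit a dimension", call. = FALSE)
  if (any(series$N < 1L))
    stop("all box counts must be >= 1", call. = FALSE)
  x <- log(1 / series$r)
  y <- log(series$N)
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  structure(unname(co[2L]), intercept = unname(co[1L]),
            residual = sqrt(mean(stats::residuals(fit)^2)))
}

#' Area of a labelled region
#'
#' Number of pixels carrying the label — the count of occupied unit boxes.
#'
#' @param labels Integer label matrix.
#' @param label Label to measure (must be present).
#' @return Integer pixel count.
#' @export
region_area <- function(labels, label) {
  n <- sum(labels == label)
  if (n == 0L) stop("label ", label, " not present", call. = FALSE)
  n
}

#' Boundary-box perimeter of a labelled region
#'
#' The region's interior holes are filled first (the estimator measures the
#' filled shape), then the pixels of the filled region with at least one
#' non-region pixel among their 4 neighbours are counted; the image border
#' counts as non-region. The count of these unit boundary boxes is the
#' perimeter, in pixel units. Digitization inflates this count relative to
#' Euclidean arc length, especially for rough or porous outlines.
#'
#' @inheritParams region_area
#' @return Integer boundary-box count.
#' @export
region_perimeter <- function(labels, label) {
  m <- matrix(as.integer(labels == label), nrow(labels))
  if (sum(m) == 0L) stop("label ", label, " not present", call. = FALSE)
  m <- fill_holes(m, Inf)
  sum(mask_boundary(m, connectivity = 4L))
}

#' Polygonal (contour-tracing) perimeter of a labelled region
#'
#' Euclidean arc length of the outer 8-connected boundary chain of the filled
#' region (steps of 1 or sqrt(2)); provided as a cross-check estimator — the
#' boundary-box count of [region_perimeter()] is the headline figure.
#'
#' @inheritParams region_area
#' @return Numeric arc length in pixels.
#' @export
region_perimeter_polygon <- function(labels, label) {
  m <- matrix(as.integer(labels == label), nrow(labels))
  if (sum(m) == 0L) stop("label ", label, " not present", call. = FALSE)
  m <- fill_holes(m, Inf)
  b <- which(mask_boundary(m, connectivity = 4L), arr.ind = TRUE)
  if (nrow(b) == 1L) return(1)
  # Moore-style greedy chaining of boundary pixels; falls back to counting
  # isolated boundary fragments if the chain breaks.
  total <- 0
  remaining <- b
  while (nrow(remaining) > 0L) {
    cur <- remaining[1L, ]
    startpt <- cur
    remaining <- remaining[-1L, , drop = FALSE]
    repeat {
      if (nrow(remaining) == 0L) break
      d <- pmax(abs(remaining[, 1L] - cur[1L]), abs(remaining[, 2L] - cur[2L]))
      j <- which(d == 1L)
      if (length(j) == 0L) break
      j <- j[which.min(abs(remaining[j, 1L] - cur[1L]) +
                         abs(remaining[j, 2L] - cur[2L]))]
      nxt <- remaining[j, ]
      total <- total + sqrt(sum((nxt - cur)^2))
      cur <- nxt
      remaining <- remaining[-j, , drop = FALSE]
    }
    total <- total + sqrt(sum((startpt - cur)^2))
  }
  total
}

#' Relative error in percent
#'
#' `100 * |estimate - reference| / reference`; the comparison metric used
#' throughout the method-vs-baseline experiments.
#'
#' @param estimate Estimated value.
#' @param reference Reference (manual / ground-truth) value, strictly positive.
#' @return Percentage error.
#' @export
relative_error <- function(estimate, reference) {
  if (any(reference <= 0))
    stop("reference must be strictly positive", call. = FALSE)
  100 * abs(estimate - reference) / reference
}

# Pad a cropped mask into the top-left corner of the next power-of-two square
# canvas (at least 16 so the dyadic ladder has >= 3 rungs).
pad_pow2 <- function(mask) {
  side <- max(16L, 2^ceiling(log2(max(dim(mask)))))
  out <- matrix(0L, side, side)
  out[seq_len(nrow(mask)), seq_len(ncol(mask))] <- mask
  out
}

#' Quantify every labelled region
#'
#' Per region: pixel area, boundary-box perimeter and box-counting fractal
#' dimension (the region's own mask cropped to its bounding box, padded to the
#' next power-of-two canvas, counted over the dyadic ladder). The bounding box
#' is reported 0-based, half-open (`row0, col0, row1, col1`).
#'
#' @param labels Integer label matrix.
#' @param config A [pipeline_config()]; `occupancy` is used (explicit
#'   `box_sizes` apply to whole-frame counting, not per-region canvases).
#' @return Data frame (`RegionStats`) with columns `label`, `area_px`,
#'   `perimeter_px`, `fractal_dimension`, `row0`, `col0`, `row1`, `col1`;
#'   empty (0-row) for an empty label image.
#' @export
quantify_all <- function(labels, config = pipeline_config()) {
  k <- max(labels)
  empty <- data.frame(label = integer(), area_px = integer(),
                      perimeter_px = integer(), fractal_dimension = numeric(),
                      row0 = integer(), col0 = integer(),
                      row1 = integer(), col1 = integer())
  if (k == 0L) return(empty)
  rows <- lapply(seq_len(k), function(l) {
    px <- which(labels == l, arr.ind = TRUE)
    if (nrow(px) == 0L) return(NULL)
    r0 <- min(px[, 1L]); r1 <- max(px[, 1L])
    c0 <- min(px[, 2L]); c1 <- max(px[, 2L])
    crop <- matrix(as.integer(labels[r0:r1, c0:c1, drop = FALSE] == l),
                   r1 - r0 + 1L)
    canvas <- pad_pow2(crop)
    # Boxes larger than about half the object saturate the count and flatten
    # the fitted slope, so the ladder stops at 2^(floor(log2(maxdim)) - 1)
    # (but keeps the 3 rungs a fit needs).
    kmax <- max(3L, as.integer(floor(log2(max(dim(crop)))) - 1L))
    sizes <- as.integer(2^seq_len(kmax))
    fd <- fractal_dimension(box_counts(canvas, sizes,
                                       occupancy = config$occupancy))
    data.frame(label = l, area_px = region_area(labels, l),
               perimeter_px = region_perimeter(labels, l),
               fractal_dimension = as.numeric(fd),
               row0 = r0 - 1L, col0 = c0 - 1L, row1 = r1, col1 = c1)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) empty else out
}
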