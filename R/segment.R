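# Texture segmentation: local entropy, thresholding, morphological
# refinement, boundary overlay, and connected-component labelling.

#' Local Shannon-entropy texture filter
#'
#' Assigns each pixel the Shannon entropy (bits) of the 256-level gray
#' histogram of its `window x window` neighbourhood (symmetric border
#' padding): `-sum(p_i * log2(p_i))` where `p_i` is the fraction of window
#' pixels quantized to level `i` and empty bins contribute 0. Textured areas
#' score high, flat areas score 0; the entropy map is the basis of the
#' texture segmentation.
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param window Odd window size (default 9, i.e. a 9x9 neighbourhood).
#' @return Matrix of entropies in bits, in `[0, 8]`.
#' @export
entropy_filter <- function(image, window = 9L) {
  stop_if_not_image(image)
  window <- check_odd_window(window, dim(image))
  q <- matrix(as.integer(round(clamp01(image) * 255)), nrow(image))
  n <- window * window
  ent <- matrix(0, nrow(image), ncol(image))
  for (level in sort(unique(as.vector(q)))) {
    cnt <- box_sum((q == level) * 1, window)
    p <- cnt / n
    contrib <- ifelse(cnt > 0, -p * log2(p), 0)
    ent <- ent + contrib
  }
  ent
}

#' Otsu threshold of a numeric image
#'
#' Maximizes between-class variance over a 256-bin histogram spanning the
#' value range. Returns the bin edge separating the two classes.
#'
#' @param x Numeric matrix or vector.
#' @param nbins Number of histogram bins (default 256).
#' @return Threshold value, or `NA` if the input is constant.
#' @export
otsu_threshold <- function(x, nbins = 256L) {
  v <- as.vector(x)
  lo <- min(v); hi <- max(v)
  if (hi <= lo) return(NA_real_)
  edges <- seq(lo, hi, length.out = nbins + 1L)
  bin <- pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1L), nbins)
  counts <- tabulate(bin, nbins)
  p <- counts / sum(counts)
  mids <- (edges[-1L] + edges[-(nbins + 1L)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  between <- rep(-Inf, nbins)
  between[valid] <- (mu_t * w0[valid] - mu[valid])^2 / (w0[valid] * w1[valid])
  k <- which.max(between)
  edges[k + 1L]
}

#' Threshold an entropy image into a binary texture mask
#'
#' A pixel is foreground iff its entropy is at least the threshold. In
#' `"otsu"` mode the threshold is chosen by maximizing between-class variance
#' over a 256-bin histogram of the entropy values; a constant entropy image
#' yields an all-zero mask with a warning. In `"fixed"` mode the supplied
#' threshold `T` is used and must lie within the entropy range.
#'
#' @param entropy_image Matrix of entropies (bits), e.g. from
#'   [entropy_filter()].
#' @param mode `"otsu"` or `"fixed"`.
#' @param T Threshold for `mode = "fixed"`.
#' @return Integer 0/1 matrix (`BinaryMask`); the threshold used is attached
#'   as attribute `"threshold"`.
#' @export
threshold_texture <- function(entropy_image, mode = c("otsu", "fixed"),
                              T = NULL) {
  mode <- match.arg(mode)
  if (mode == "otsu") {
    thr <- otsu_threshold(entropy_image)
    if (is.na(thr)) {
      warning("constant entropy image: returning an empty mask", call. = FALSE)
      return(structure(matrix(0L, nrow(entropy_image), ncol(entropy_image)),
                       threshold = NA_real_))
    }
  } else {
    if (is.null(T)) stop("mode 'fixed' requires a threshold T", call. = FALSE)
    if (T < min(entropy_image) || T > max(entropy_image))
      stop("fixed threshold ", T, " lies outside the entropy range [",
           signif(min(entropy_image), 4), ", ", signif(max(entropy_image), 4),
           "]", call. = FALSE)
    thr <- T
  }
  mask <- matrix(as.integer(entropy_image >= thr), nrow(entropy_image))
  structure(mask, threshold = thr)
}

# --- connected components ----------------------------------------------------

# Run-based two-pass labelling with union-find; connectivity 4 or 8.
# Runs are maximal vertical strips of foreground within each column
# (column-major storage makes these contiguous); runs in adjacent columns are
# merged when any of their pixels are neighbours under the connectivity.
label_components <- function(mask, connectivity = 8L) {
  h <- nrow(mask); w <- ncol(mask)
  fg <- mask != 0
  out <- matrix(0L, h, w)
  if (!any(fg)) return(out)
  v <- as.vector(fg)
  start <- v & !c(FALSE, v[-length(v)])
  start[seq(1L, length(v), by = h)] <- v[seq(1L, length(v), by = h)]
  run_id <- integer(length(v))
  run_id[v] <- cumsum(start)[v]
  nrun <- max(run_id)
  run_mat <- matrix(run_id, h, w)

  parent <- seq_len(nrun)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  offsets <- if (connectivity == 8L) c(-1L, 0L, 1L) else 0L
  pairs <- NULL
  if (w > 1L) {
    left <- run_mat[, -w, drop = FALSE]
    right <- run_mat[, -1L, drop = FALSE]
    for (dr in offsets) {
      a <- left; b <- right
      if (dr == -1L) { a <- a[-1L, , drop = FALSE]; b <- b[-h, , drop = FALSE] }
      if (dr ==  1L) { a <- a[-h, , drop = FALSE]; b <- b[-1L, , drop = FALSE] }
      sel <- a > 0L & b > 0L
      if (any(sel)) pairs <- rbind(pairs, unique(cbind(a[sel], b[sel])))
    }
  }
  if (!is.null(pairs)) {
    pairs <- unique(pairs)
    for (k in seq_len(nrow(pairs))) {
      ra <- find(pairs[k, 1L]); rb <- find(pairs[k, 2L])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(nrun), find, integer(1L))
  labels <- match(root, sort(unique(root)))
  out[fg] <- labels[run_id[v]]
  out
}

#' Label the connected regions of a binary mask
#'
#' 8-connected component labelling; labels are contiguous from 1 and ordered
#' by decreasing region area (ties broken by the topmost-leftmost pixel).
#'
#' @param mask Integer 0/1 matrix.
#' @return Integer label matrix (`LabelImage`), 0 = background.
#' @export
label_regions <- function(mask) {
  stop_if_not_mask(mask)
  lab <- label_components(mask, connectivity = 8L)
  k <- max(lab)
  if (k == 0L) return(lab)
  areas <- tabulate(lab[lab > 0L], k)
  first_px <- vapply(seq_len(k), function(l) which(lab == l)[1L], integer(1L))
  ord <- order(-areas, first_px)
  remap <- integer(k)
  remap[ord] <- seq_len(k)
  out <- lab
  out[lab > 0L] <- remap[lab[lab > 0L]]
  out
}

# Fill background holes (4-connected complement components not touching the
# border) smaller than min_size; min_size = Inf fills all holes.
fill_holes <- function(mask, min_size = Inf) {
  comp <- label_components(1L - mask, connectivity = 4L)
  k <- max(comp)
  if (k == 0L) return(mask)
  border <- unique(c(comp[1L, ], comp[nrow(comp), ], comp[, 1L],
                     comp[, ncol(comp)]))
  border <- border[border > 0L]
  areas <- tabulate(comp[comp > 0L], k)
  fill <- setdiff(which(areas < min_size), border)
  out <- mask
  out[comp %in% fill] <- 1L
  out
}

#' Morphological refinement of a texture mask
#'
#' Applies, in order: morphological opening with a disk structuring element of
#' the given radius (removes protrusions and bridges thinner than the disk);
#' removal of 8-connected components smaller than `min_size` pixels; filling
#' of interior holes smaller than `min_size`. The result is the refined mask
#' `I_M` used for boundary extraction and quantification.
#'
#' @param mask Integer 0/1 matrix.
#' @param min_size Minimum surviving component (and hole) area in pixels.
#' @param radius Disk radius of the structuring element (pixels).
#' @return Refined 0/1 matrix.
#' @export
refine_mask <- function(mask, min_size = 64L, radius = 2L) {
  stop_if_not_mask(mask)
  if (min_size < 0L) stop("min_size must be >= 0", call. = FALSE)
  if (radius < 1L) stop("radius must be >= 1", call. = FALSE)
  brush <- EBImage::makeBrush(2L * radius + 1L, shape = "disc")
  opened <- EBImage::imageData(EBImage::opening(mask, brush))
  opened <- matrix(as.integer(opened > 0), nrow(mask))
  if (min_size > 0L) {
    lab <- label_components(opened, connectivity = 8L)
    if (max(lab) > 0L) {
      areas <- tabulate(lab[lab > 0L], max(lab))
      small <- which(areas < min_size)
      opened[lab %in% small] <- 0L
    }
    opened <- fill_holes(opened, min_size)
  }
  opened
}

#' Superimpose segmentation boundaries on an image
#'
#' The boundary set consists of mask pixels with at least one background pixel
#' among their 8 neighbours (the image border counts as background) — where
#' the 3x3 local range of the mask is 1. Those pixels are set to 1.0 in a copy
#' of the image, producing the segmented image `I_S`.
#'
#' @param image Numeric matrix.
#' @param mask Integer 0/1 matrix of the same shape.
#' @return The image with boundary pixels set to 1.0.
#' @export
boundary_overlay <- function(image, mask) {
  stop_if_not_image(image)
  stop_if_not_mask(mask)
  if (!identical(dim(image), dim(mask)))
    stop("image and mask shapes differ", call. = FALSE)
  out <- image
  out[mask_boundary(mask, connectivity = 8L)] <- 1.0
  out
}

# Logical matrix of mask pixels adjacent (4- or 8-) to background; the
# outside of the frame counts as background.
mask_boundary <- function(mask, connectivity = 8L) {
  offs <- if (connectivity == 8L)
    list(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, -1L),
         c(0L, 1L), c(1L, -1L), c(1L, 0L), c(1L, 1L))
  else list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  nbmin <- matrix(1L, nrow(mask), ncol(mask))
  for (o in offs)
    nbmin <- pmin(nbmin, shift_matrix(mask, o[1L], o[2L], fill = 0L))
  mask == 1L & nbmin == 0L
}

#' Watershed baseline segmentation
#'
#' Conventional gradient-flooding watershed used as the comparison arm: the
#' image gradient magnitude is smoothed (Gaussian, `sigma = 2`), inverted and
#' flooded with [EBImage::watershed()]; shallow basins (depth below
#' `tolerance`) and basins closer than `min_marker_distance` are merged.
#' Basins whose mean image intensity falls below an Otsu split of the basin
#' means are relabelled as background (label 0); remaining basins are
#' relabelled 1..K by decreasing area.
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param min_marker_distance Neighbourhood radius (pixels) for marker
#'   suppression.
#' @param tolerance Minimum basin depth (in units of the normalized gradient).
#' @param smooth_sigma Gaussian sigma applied to the gradient magnitude.
#' @return Integer label matrix (`LabelImage`); 0 = background.
#' @export
watershed_baseline <- function(image, min_marker_distance = 5L,
                               tolerance = 0.1, smooth_sigma = 2) {
  stop_if_not_image(image)
  if (min_marker_distance < 1L)
    stop("min_marker_distance must be >= 1", call. = FALSE)
  gx <- (shift_matrix(image, 0L, -1L, NA) - shift_matrix(image, 0L, 1L, NA)) / 2
  gy <- (shift_matrix(image, -1L, 0L, NA) - shift_matrix(image, 1L, 0L, NA)) / 2
  g <- sqrt(ifelse(is.na(gx), 0, gx)^2 + ifelse(is.na(gy), 0, gy)^2)
  g <- EBImage::imageData(EBImage::gblur(g, sigma = smooth_sigma))
  rng <- max(g) - min(g)
  if (rng == 0) return(matrix(0L, nrow(image), ncol(image)))
  g <- (g - min(g)) / rng
  basins <- EBImage::imageData(EBImage::watershed(1 - g, tolerance = tolerance,
                                                  ext = min_marker_distance))
  basins <- matrix(as.integer(basins), nrow(image))
  k <- max(basins)
  if (k == 0L) return(basins)
  means <- vapply(seq_len(k), function(l) mean(image[basins == l]), numeric(1L))
  thr <- otsu_threshold(means, nbins = 64L)
  keep <- if (is.na(thr)) integer(0) else which(means >= thr)
  out <- matrix(0L, nrow(image), ncol(image))
  if (length(keep) == 0L) return(out)
  areas <- tabulate(basins[basins > 0L], k)
  ord <- keep[order(-areas[keep])]
  for (i in seq_along(ord)) out[basins == ord[i]] <- i
  out
}
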