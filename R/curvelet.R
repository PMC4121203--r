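# Tight-frame discrete curvelet transform.
#
# The frequency plane is partitioned into a low-pass disk plus J-1 dyadic
# annuli; every annulus is split into smooth angular wedges whose count
# doubles every other scale. Radial and angular windows are built from the
# Meyer transition polynomial so that the sum of squared windows is 1
# everywhere (partition of unity): the frame is tight, hence the transform is
# exactly invertible and energy-preserving up to floating-point rounding.
# Coefficient bands are kept at the full image resolution; windows are stored
# sparsely on their frequency support.

.curvelet_cache <- new.env(parent = emptyenv())

# Meyer transition polynomial: C^3 ramp with nu(t) + nu(1 - t) = 1.
meyer_nu <- function(t) {
  t <- pmin(pmax(t, 0), 1)
  t^4 * (35 - 84 * t + 70 * t^2 - 20 * t^3)
}

# Orientation count at detail scale j (j = 2 coarsest detail): doubles every
# other scale moving finer.
n_orientations <- function(j, angles_coarse) {
  as.integer(angles_coarse * 2^((j - 2L) %/% 2L))
}

# Build (and cache) the sparse frequency windows for one image shape.
curvelet_windows <- function(h, w, scales, angles_coarse) {
  key <- paste(h, w, scales, angles_coarse, sep = "x")
  hit <- get0(key, envir = .curvelet_cache)
  if (!is.null(hit)) return(hit)

  fr <- ifelse(seq_len(h) - 1L <= h %/% 2L, seq_len(h) - 1L,
               seq_len(h) - 1L - h) / h
  fc <- ifelse(seq_len(w) - 1L <= w %/% 2L, seq_len(w) - 1L,
               seq_len(w) - 1L - w) / w
  FR <- matrix(fr, h, w)
  FC <- matrix(fc, h, w, byrow = TRUE)
  r <- sqrt(FR^2 + FC^2)
  theta <- atan2(FR, FC)
  log2r <- ifelse(r > 0, log2(r), -Inf)

  # Radial transition at cut t_j = 2^(j - J) / 2 spans one octave centred on
  # the cut; adjacent transitions abut without overlapping, so squares of the
  # rising/falling pair telescope to exactly 1.
  J <- scales
  rise <- vector("list", J - 1L)
  fall <- vector("list", J - 1L)
  for (j in seq_len(J - 1L)) {
    cut <- 0.5 * 2^(j - J)
    u <- meyer_nu(log2r - (log2(cut) - 0.5))
    rise[[j]] <- sin(pi / 2 * u)
    fall[[j]] <- cos(pi / 2 * u)
  }
  radial <- vector("list", J)
  radial[[1L]] <- fall[[1L]]
  if (J > 2L) for (j in 2:(J - 1L)) radial[[j]] <- rise[[j - 1L]] * fall[[j]]
  radial[[J]] <- rise[[J - 1L]]

  bands <- vector("list", J)
  bands[[1L]] <- {
    idx <- which(radial[[1L]] > 0)
    list(list(idx = idx, w = radial[[1L]][idx]))
  }
  for (j in 2:J) {
    n <- n_orientations(j, angles_coarse)
    ann <- which(radial[[j]] > 0)
    th <- theta[ann]
    rad <- radial[[j]][ann]
    sc <- vector("list", n)
    for (l in seq_len(n)) {
      centre <- -pi + 2 * pi * (l - 1L) / n
      s <- (th - centre) * n / (2 * pi)
      s <- s - round(s / n) * n            # wrap to [-n/2, n/2)
      v <- cos(pi / 2 * meyer_nu(abs(s)))
      keep <- which(abs(s) < 1)
      sc[[l]] <- list(idx = ann[keep], w = rad[keep] * v[keep])
    }
    bands[[j]] <- sc
  }
  out <- list(shape = c(h, w), scales = J, angles_coarse = angles_coarse,
              bands = bands)
  assign(key, out, envir = .curvelet_cache)
  out
}

#' Forward discrete curvelet transform
#'
#' Decomposes an image into a multiscale, multi-orientation pyramid of complex
#' coefficient grids via smooth frequency wedges (see the package vignette for
#' the construction). The frame is tight: [ifdct()] reconstructs the input to
#' machine precision and total coefficient energy equals image energy
#' (Parseval).
#'
#' @param image Numeric matrix.
#' @param scales Number of scales `J >= 2`; `NULL` selects
#'   `max(4, ceiling(log2(min(H, W))) - 3)` clamped to `floor(log2(min(H, W)))`.
#' @param angles_coarse Orientations at the coarsest detail scale (8, 16 or 32).
#' @return A `curvelet_pyramid`: `scales[[1]]` holds the single low-pass band,
#'   `scales[[j]]` for `j > 1` a list of orientation bands (complex matrices of
#'   the source shape); attributes record the geometry.
#' @export
fdct <- function(image, scales = NULL, angles_coarse = 16L) {
  stop_if_not_image(image)
  h <- nrow(image); w <- ncol(image)
  if (is.null(scales)) scales <- resolve_scales(pipeline_config(), c(h, w))
  scales <- as.integer(scales)
  if (scales < 2L) stop("scales must be >= 2", call. = FALSE)
  if (!angles_coarse %in% c(8L, 16L, 32L))
    stop("angles_coarse must be 8, 16 or 32", call. = FALSE)
  if (min(h, w) < 2^scales)
    stop("image of size ", h, "x", w, " is too small for ", scales,
         " scales; use at most ", floor(log2(min(h, w))), call. = FALSE)
  win <- curvelet_windows(h, w, scales, angles_coarse)
  Fhat <- stats::fft(image)
  hw <- h * w
  pyr <- vector("list", scales)
  for (j in seq_len(scales)) {
    pyr[[j]] <- lapply(win$bands[[j]], function(b) {
      Z <- matrix(0i, h, w)
      Z[b$idx] <- Fhat[b$idx] * b$w
      stats::fft(Z, inverse = TRUE) / hw
    })
  }
  structure(list(scales = pyr, source_shape = c(h, w)),
            n_scales = scales, angles_coarse = as.integer(angles_coarse),
            class = "curvelet_pyramid")
}

check_pyramid <- function(pyramid) {
  if (!inherits(pyramid, "curvelet_pyramid"))
    stop("expected a curvelet_pyramid", call. = FALSE)
  sh <- pyramid$source_shape
  for (j in seq_along(pyramid$scales)) {
    for (band in pyramid$scales[[j]]) {
      if (!identical(dim(band), as.integer(sh)))
        stop("band shape does not match source_shape ",
             paste(sh, collapse = "x"), call. = FALSE)
    }
  }
  invisible(pyramid)
}

# Reconstruct from a subset of scales (adjoint of the tight frame).
reconstruct_scales <- function(pyramid, keep) {
  check_pyramid(pyramid)
  sh <- pyramid$source_shape
  h <- sh[1L]; w <- sh[2L]; hw <- h * w
  J <- attr(pyramid, "n_scales")
  win <- curvelet_windows(h, w, J, attr(pyramid, "angles_coarse"))
  G <- matrix(0i, h, w)
  for (j in keep) {
    bw <- win$bands[[j]]
    cb <- pyramid$scales[[j]]
    for (l in seq_along(cb)) {
      FB <- stats::fft(cb[[l]])
      idx <- bw[[l]]$idx
      G[idx] <- G[idx] + FB[idx] * bw[[l]]$w
    }
  }
  out <- stats::fft(G, inverse = TRUE) / hw
  resid <- max(abs(Im(out)))
  if (resid > 1e-8)
    warning("imaginary residue ", signif(resid, 3),
            " in curvelet reconstruction", call. = FALSE)
  Re(out)
}

#' Inverse discrete curvelet transform
#'
#' Reconstructs the spatial image from a pyramid. For an unmodified pyramid
#' the result equals the forward input to within 1e-6 (tight frame); modified
#' pyramids may reconstruct to values outside `[0, 1]` — no clipping is
#' applied.
#'
#' @param pyramid A `curvelet_pyramid`.
#' @return Real-valued matrix of the pyramid's source shape.
#' @export
ifdct <- function(pyramid) {
  reconstruct_scales(pyramid, seq_along(pyramid$scales))
}

#' High-pass (detail) image from the finest curvelet scale
#'
#' Reconstructs using only the finest-scale orientation bands, zeroing all
#' coarser scales: the detail image `I_HP`. It carries edge and singularity
#' structure and no DC component (zero mean to within 1e-6).
#'
#' @param pyramid A `curvelet_pyramid`.
#' @return Real-valued matrix; typically signed.
#' @export
highpass_image <- function(pyramid) {
  reconstruct_scales(pyramid, length(pyramid$scales))
}

#' Coefficient energy of a pyramid (or one of its scales)
#'
#' @param pyramid A `curvelet_pyramid`.
#' @param scales Scales to include (default all).
#' @return Sum of squared coefficient moduli.
#' @export
pyramid_energy <- function(pyramid, scales = seq_along(pyramid$scales)) {
  tot <- 0
  for (j in scales)
    for (band in pyramid$scales[[j]])
      tot <- tot + sum(Mod(band)^2)
  tot
}

#' @export
print.curvelet_pyramid <- function(x, ...) {
  J <- attr(x, "n_scales")
  cat("curvelet_pyramid:", paste(x$source_shape, collapse = "x"),
      "image,", J, "scales\n")
  for (j in seq_len(J))
    cat("  scale", j, ":", length(x$scales[[j]]), "orientation band(s)\n")
  invisible(x)
}
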