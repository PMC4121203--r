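# Deterministic generator of SEM-like test scenes with exact ground truth:
# bright particles with internal band-passed texture on a darker, more weakly
# textured background, Gaussian blur, additive Gaussian noise. Ground truth
# (labels, areas, boundary-box perimeters) is taken from the pre-blur,
# pre-noise rasterization, i.e. it measures the true object, not its
# degraded image.

#' Specify a synthetic scene
#'
#' @param shapes List of shape descriptors. Each is a list with a `kind`
#'   (`"disk"`, `"ellipse"`, `"blob"`, `"square"`, `"line"`, `"sierpinski"`),
#'   an `intensity` in `[0, 1]`, and geometry in pixels: `center` + `radius`
#'   (disk, blob), `center` + `axes` + optional `angle` in radians (ellipse),
#'   `center` + `side` (square), `from` + `to` (line), `corner` + `depth`
#'   (sierpinski carpet of side `3^depth`). Blobs accept `irregularity`
#'   (default 0.25) and `lobes` (default 5).
#' @param size Frame size `c(H, W)`.
#' @param background_intensity Background gray level.
#' @param texture_amplitude Standard deviation of the band-passed texture
#'   inside particles (intensity units).
#' @param background_texture_amplitude Texture amplitude of the background
#'   (default a quarter of the particle amplitude).
#' @param blur_sigma Gaussian blur applied to the composed scene (0 = none).
#' @param noise_sigma Standard deviation of the additive Gaussian noise.
#' @param seed Integer seed; the scene is a pure function of the spec.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(shapes, size = c(256L, 256L),
                       background_intensity = 0.2,
                       texture_amplitude = 0.15,
                       background_texture_amplitude = texture_amplitude / 4,
                       blur_sigma = 1, noise_sigma = 0.03, seed = 1L) {
  spec <- list(shapes = shapes, size = as.integer(size),
               background_intensity = background_intensity,
               texture_amplitude = texture_amplitude,
               background_texture_amplitude = background_texture_amplitude,
               blur_sigma = blur_sigma, noise_sigma = noise_sigma,
               seed = as.integer(seed))
  for (s in shapes) validate_shape(s, spec$size)
  class(spec) <- "scene_spec"
  spec
}

validate_shape <- function(s, size) {
  reach <- switch(s$kind,
    disk = s$radius,
    blob = s$radius * (1 + (if (is.null(s$irregularity)) 0.25 else s$irregularity)),
    ellipse = max(s$axes),
    square = s$side / 2,
    line = 0,
    sierpinski = 0,
    stop("unknown shape kind '", s$kind, "'", call. = FALSE))
  ctr <- switch(s$kind,
    line = rbind(s$from, s$to),
    sierpinski = rbind(s$corner, s$corner + 3^s$depth - 1L),
    matrix(s$center, 1L))
  if (any(ctr - reach < 1) || any(ctr[, 1L] + reach > size[1L]) ||
      any(ctr[, 2L] + reach > size[2L]))
    stop("shape of kind '", s$kind, "' does not fit within the ",
         size[1L], "x", size[2L], " frame", call. = FALSE)
  invisible(s)
}

# Rasterize one shape to a logical footprint. Pixel (i, j) covers the point
# (i, j) in row/column coordinates; any RNG use (blob outlines) draws from
# the current stream.
rasterize_shape <- function(s, h, w) {
  R <- matrix(seq_len(h), h, w)
  C <- matrix(seq_len(w), h, w, byrow = TRUE)
  switch(s$kind,
    disk = (R - s$center[1L])^2 + (C - s$center[2L])^2 <= s$radius^2,
    square = {
      half <- s$side / 2
      R > s$center[1L] - half & R <= s$center[1L] + half &
        C > s$center[2L] - half & C <= s$center[2L] + half
    },
    ellipse = {
      a <- if (is.null(s$angle)) 0 else s$angle
      dr <- R - s$center[1L]; dc <- C - s$center[2L]
      u <- dr * cos(a) + dc * sin(a)
      v <- -dr * sin(a) + dc * cos(a)
      (u / s$axes[1L])^2 + (v / s$axes[2L])^2 <= 1
    },
    blob = {
      irr <- if (is.null(s$irregularity)) 0.25 else s$irregularity
      lobes <- if (is.null(s$lobes)) 5L else s$lobes
      amp <- stats::runif(lobes, 0.3, 1) * irr / lobes
      ph <- stats::runif(lobes, 0, 2 * pi)
      dr <- R - s$center[1L]; dc <- C - s$center[2L]
      phi <- atan2(dr, dc)
      rad <- s$radius * (1 + Reduce(`+`, lapply(seq_len(lobes), function(k)
        amp[k] * cos((k + 1L) * phi + ph[k]))))
      dr^2 + dc^2 <= rad^2
    },
    line = {
      pts <- bresenham(s$from, s$to)
      m <- matrix(FALSE, h, w)
      m[pts] <- TRUE
      m
    },
    sierpinski = {
      side <- 3^s$depth
      m <- matrix(FALSE, h, w)
      m[s$corner[1L]:(s$corner[1L] + side - 1L),
        s$corner[2L]:(s$corner[2L] + side - 1L)] <- sierpinski_mask(s$depth)
      m
    })
}

#' Sierpinski-carpet mask
#'
#' Binary `3^depth` square: a pixel belongs to the carpet iff no base-3 digit
#' pair of its (0-based) coordinates is (1, 1). The carpet's box-counting
#' dimension is `log(8)/log(3) = 1.8928`, an exact reference for fractal
#' dimension recovery.
#'
#' @param depth Recursion depth (>= 1).
#' @return Logical matrix of side `3^depth`.
#' @export
sierpinski_mask <- function(depth) {
  side <- 3^depth
  idx <- seq_len(side) - 1L
  keep <- matrix(TRUE, side, side)
  for (k in seq_len(depth) - 1L) {
    di <- (idx %/% 3^k) %% 3L
    keep <- keep & !outer(di == 1L, di == 1L, `&`)
  }
  keep
}

bresenham <- function(from, to) {
  n <- max(abs(to - from)) + 1L
  cbind(round(seq(from[1L], to[1L], length.out = n)),
        round(seq(from[2L], to[2L], length.out = n)))
}

band_passed_noise <- function(h, w, sigma_lo = 1, sigma_hi = 3) {
  z <- matrix(stats::rnorm(h * w), h, w)
  b <- EBImage::imageData(EBImage::gblur(z, sigma = sigma_lo)) -
    EBImage::imageData(EBImage::gblur(z, sigma = sigma_hi))
  b / stats::sd(b)
}

#' Generate a synthetic SEM-like scene with exact ground truth
#'
#' Shapes are rasterized back-to-front (later shapes occlude earlier ones for
#' label ownership, so every pixel has exactly one true label), per-region
#' band-passed texture is added, the scene is blurred and Gaussian noise is
#' added, and the result is clipped to `[0, 1]`. Ground truth is computed
#' from the pre-blur, pre-noise rasterization.
#'
#' @param spec A [scene_spec()].
#' @return A list of class `curvseg_scene`: `image` (matrix in `[0, 1]`),
#'   `truth` with `label_image`, a `regions` data frame (`label`, `area_px`,
#'   `perimeter_px`, analytic area/perimeter where the shape has a closed
#'   form, `overlap` flag) and an `overlaps` data frame of realized pairwise
#'   overlap fractions (intersection over the smaller footprint), and `spec`.
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  h <- spec$size[1L]; w <- spec$size[2L]
  with_seed(spec$seed, {
    footprints <- lapply(spec$shapes, rasterize_shape, h = h, w = w)
    lab <- matrix(0L, h, w)
    for (i in seq_along(footprints)) lab[footprints[[i]]] <- i

    ns <- length(footprints)
    ov <- NULL
    if (ns > 1L) {
      for (i in seq_len(ns - 1L)) for (j in (i + 1L):ns) {
        inter <- sum(footprints[[i]] & footprints[[j]])
        if (inter > 0L) {
          f <- inter / min(sum(footprints[[i]]), sum(footprints[[j]]))
          ov <- rbind(ov, data.frame(i = i, j = j, fraction = f))
        }
      }
    }
    if (is.null(ov)) ov <- data.frame(i = integer(), j = integer(),
                                      fraction = numeric())

    present <- sort(unique(lab[lab > 0L]))
    relab <- matrix(0L, h, w)
    regions <- NULL
    for (new in seq_along(present)) {
      old <- present[new]
      relab[lab == old] <- new
      s <- spec$shapes[[old]]
      an_area <- switch(s$kind, disk = pi * s$radius^2,
                        square = s$side^2,
                        ellipse = pi * prod(s$axes), NA_real_)
      an_per <- switch(s$kind, disk = 2 * pi * s$radius,
                       square = 4 * s$side, NA_real_)
      regions <- rbind(regions, data.frame(
        label = new, kind = s$kind,
        area_px = sum(relab == new),
        perimeter_px = region_perimeter(relab, new),
        analytic_area = an_area, analytic_perimeter = an_per,
        overlap = old %in% c(ov$i, ov$j)))
    }
    if (is.null(regions))
      regions <- data.frame(label = integer(), kind = character(),
                            area_px = integer(), perimeter_px = integer(),
                            analytic_area = numeric(),
                            analytic_perimeter = numeric(),
                            overlap = logical())

    img <- matrix(spec$background_intensity, h, w)
    if (spec$background_texture_amplitude > 0)
      img <- img + spec$background_texture_amplitude * band_passed_noise(h, w)
    for (i in seq_along(spec$shapes)) {
      own <- lab == i
      if (!any(own)) next
      tex <- if (spec$texture_amplitude > 0)
        spec$texture_amplitude * band_passed_noise(h, w) else 0
      base <- spec$shapes[[i]]$intensity
      img[own] <- base + (if (is.matrix(tex)) tex[own] else 0)
    }
    if (spec$blur_sigma > 0)
      img <- EBImage::imageData(EBImage::gblur(img, sigma = spec$blur_sigma,
                                               boundary = "replicate"))
    if (spec$noise_sigma > 0)
      img <- img + matrix(stats::rnorm(h * w, 0, spec$noise_sigma), h, w)
    img <- clamp01(img)

    structure(list(image = img,
                   truth = list(label_image = relab, regions = regions,
                                overlaps = ov),
                   spec = spec),
              class = "curvseg_scene")
  })
}

# Circle-circle lens area divided by the smaller circle's area.
lens_fraction <- function(r1, r2, d) {
  if (d >= r1 + r2) return(0)
  if (d <= abs(r1 - r2)) return(1)
  a1 <- r1^2 * acos((d^2 + r1^2 - r2^2) / (2 * d * r1))
  a2 <- r2^2 * acos((d^2 + r2^2 - r1^2) / (2 * d * r2))
  tri <- 0.5 * sqrt(max(0, (-d + r1 + r2) * (d + r1 - r2) *
                          (d - r1 + r2) * (d + r1 + r2)))
  (a1 + a2 - tri) / (pi * min(r1, r2)^2)
}

# Distance between two circle centres realizing a given overlap fraction.
overlap_distance <- function(r1, r2, fraction) {
  if (fraction <= 0) return(r1 + r2 + 2)
  stats::uniroot(function(d) lens_fraction(r1, r2, d) - fraction,
                 lower = abs(r1 - r2) + 1e-6, upper = r1 + r2 - 1e-6)$root
}

#' Suite of overlapping-particle scenes
#'
#' Deterministic batch of scenes, each with 3–8 textured disk particles whose
#' pairwise overlaps are drawn from 0–40% of the smaller particle's area
#' (every scene contains at least one overlapping pair), with additive noise.
#' The suite probes the failure mode segmentation methods exhibit on
#' overlapping and connected particles.
#'
#' Particles model a single-material specimen: they share one base
#' brightness (`particle_intensity`), and differ only in their internal
#' texture realization — brightness in an SEM micrograph tracks material and
#' topography, not particle identity.
#'
#' @param seed Integer master seed; each scene derives its own sub-seed.
#' @param n_scenes Number of scenes (>= 1).
#' @param size Frame size `c(H, W)`.
#' @param noise_sigma Additive noise level (default 0.03).
#' @param particle_intensity Common base brightness of the particles.
#' @return List of `curvseg_scene` objects.
#' @export
overlap_suite <- function(seed, n_scenes, size = c(224L, 224L),
                          noise_sigma = 0.03, particle_intensity = 0.7) {
  if (n_scenes < 1L) stop("n_scenes must be >= 1", call. = FALSE)
  lapply(seq_len(n_scenes), function(k) {
    sub <- (as.integer(seed) * 1000L + k) %% 2147483647L
    shapes <- with_seed(sub, {
      h <- size[1L]; w <- size[2L]
      np <- sample(3:8, 1L)
      radii <- round(stats::runif(np, 14, 24))
      margin <- radii + 2
      # Overlaps are realized as disjoint pairs: a particle overlaps at most
      # one partner, by 5-40% of the smaller area. Particles not in a pair
      # keep a 12 px clearance (beyond the reach of the 9x9 analysis window)
      # so that "non-overlapping" is unambiguous at analysis time.
      gap <- 12
      centers <- matrix(NA_real_, np, 2L)
      paired <- logical(np)
      centers[1L, ] <- c(stats::runif(1, margin[1L], h - margin[1L]),
                         stats::runif(1, margin[1L], w - margin[1L]))
      clear_of <- function(cand, i, except = 0L, slack = gap) {
        for (k in seq_len(i - 1L)) {
          if (k == except) next
          d <- sqrt(sum((cand - centers[k, ])^2))
          if (d < radii[i] + radii[k] + slack) return(FALSE)
        }
        TRUE
      }
      in_frame <- function(cand, i)
        cand[1L] >= margin[i] && cand[1L] <= h - margin[i] &&
        cand[2L] >= margin[i] && cand[2L] <= w - margin[i]
      for (i in 2:np) {
        force_overlap <- (i == np && !any(paired))
        free <- which(!paired[seq_len(i - 1L)])
        do_overlap <- (force_overlap || stats::runif(1) < 0.5) &&
          length(free) > 0L
        placed <- FALSE
        if (do_overlap) {
          for (att in 1:100) {
            j <- if (length(free) == 1L) free else sample(free, 1L)
            f <- if (force_overlap) stats::runif(1, 0.2, 0.4)
                 else stats::runif(1, 0.05, 0.4)
            d <- overlap_distance(radii[j], radii[i], f)
            ang <- stats::runif(1, 0, 2 * pi)
            cand <- centers[j, ] + d * c(sin(ang), cos(ang))
            if (in_frame(cand, i) && clear_of(cand, i, except = j)) {
              centers[i, ] <- cand
              paired[c(i, j)] <- TRUE
              placed <- TRUE
              break
            }
          }
        }
        if (!placed) {
          for (slack in c(gap, 6, 3)) {
            for (att in 1:200) {
              cand <- c(stats::runif(1, margin[i], h - margin[i]),
                        stats::runif(1, margin[i], w - margin[i]))
              if (clear_of(cand, i, slack = slack)) {
                centers[i, ] <- cand
                placed <- TRUE
                break
              }
            }
            if (placed) break
          }
          if (!placed)
            centers[i, ] <- c(stats::runif(1, margin[i], h - margin[i]),
                              stats::runif(1, margin[i], w - margin[i]))
        }
      }
      lapply(seq_len(np), function(i)
        list(kind = "disk", center = round(centers[i, ]), radius = radii[i],
             intensity = particle_intensity))
    })
    generate_scene(scene_spec(shapes, size = size, noise_sigma = noise_sigma,
                              seed = sub))
  })
}
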