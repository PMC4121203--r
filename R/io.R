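#' Read a grayscale image
#'
#' Reads an 8- or 16-bit PNG or TIFF image and returns it as a numeric matrix
#' of intensities in `[0, 1]` (row-major, origin at the top-left). RGB input
#' is converted to luminance with the ITU-R BT.601 weights
#' (0.2989, 0.5870, 0.1140); an alpha channel, if present, is dropped.
#' Intensities are rescaled by the source dtype maximum, so pixel ordering is
#' preserved exactly.
#'
#' @param path Path to a PNG or TIFF file.
#' @return A numeric matrix (`GrayImage`) with values in `[0, 1]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path))
    stop("image file does not exist: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = try(png::readPNG(path), silent = TRUE),
    tif = ,
    tiff = try(tiff::readTIFF(path), silent = TRUE),
    stop("unsupported image format '", ext, "' for ", path,
         " (PNG or TIFF expected)", call. = FALSE)
  )
  if (inherits(arr, "try-error"))
    stop("could not read image file ", path, call. = FALSE)
  to_gray(arr)
}

# Collapse a decoded PNG/TIFF array (already scaled to [0,1] by dtype max)
# to a single-channel matrix using BT.601 luminance.
to_gray <- function(arr) {
  if (is.matrix(arr)) return(unname(arr))
  if (length(dim(arr)) == 3L) {
    nc <- dim(arr)[3L]
    if (nc == 2L) return(unname(arr[, , 1L]))          # gray + alpha
    if (nc >= 3L) {
      w <- c(0.2989, 0.5870, 0.1140)
      return(unname(arr[, , 1L] * w[1L] + arr[, , 2L] * w[2L] + arr[, , 3L] * w[3L]))
    }
    return(unname(arr[, , 1L]))
  }
  stop("unsupported image array layout", call. = FALSE)
}

#' Write a grayscale image as 8-bit PNG
#'
#' Values are clipped to `[0, 1]` and quantized to 8 bits. Writing then
#' reading an image whose values are exact multiples of 1/255 is lossless.
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param path Output PNG path.
#' @return Invisibly, `path`.
#' @export
write_image <- function(image, path) {
  stop_if_not_image(image)
  png::writePNG(clamp01(image), target = path)
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles every tunable of the analysis pipeline with validated defaults.
#' All lengths are in pixels; `scale_um_per_px` is an uninterpreted
#' pass-through for downstream unit conversion.
#'
#' @param entropy_window Odd window (pixels) of the local entropy filter
#'   (default 9, i.e. a 9x9 neighbourhood).
#' @param texture_threshold_mode `"otsu"` (automatic) or `"fixed"`.
#' @param texture_threshold Threshold used when `texture_threshold_mode` is
#'   `"fixed"`, on the entropy scale (bits).
#' @param min_object_size Components (and holes) smaller than this many
#'   pixels are removed (filled) during mask refinement.
#' @param struct_elem_radius Radius of the disk structuring element used for
#'   morphological opening.
#' @param curvelet_scales Number of curvelet scales `J`; `NULL` selects
#'   `max(4, ceiling(log2(min(H, W))) - 3)` per image (clamped so the image
#'   still fits `2^J`).
#' @param curvelet_angles_coarse Orientations at the coarsest detail scale;
#'   one of 8, 16, 32.
#' @param box_sizes Box side lengths for box counting; `NULL` selects the
#'   dyadic ladder `2^k`, `k = 1, ..., floor(log2(min(H, W))) - 1`.
#' @param wiener_window Odd window of the adaptive Wiener denoiser.
#' @param seed Integer seed routing all randomness of a run.
#' @param hp_gain Gain applied to the high-pass detail image before adding it
#'   back (1 reproduces plain addition).
#' @param hp_source `"denoised"` (default) or `"raw"`: which image the
#'   curvelet transform is taken of when forming the detail image.
#' @param overlay_on `"enhanced"` or `"entropy"`: image the segmentation
#'   boundaries are painted on.
#' @param occupancy `"ge1"` (a box is occupied by at least one foreground
#'   pixel; standard) or `"gt1"` (strictly more than one).
#' @param entropy_support_correction If `TRUE` (default), the thresholded
#'   texture mask is eroded by a disk of the entropy window's half-width
#'   before refinement. A windowed entropy detector responds as soon as its
#'   window touches textured structure, so its foreground is the true region
#'   dilated by the window half-width; the erosion removes exactly that
#'   systematic support bias.
#' @param watershed_tolerance Minimum basin depth (intensity units) below
#'   which adjacent watershed basins are merged.
#' @param min_marker_distance Neighbourhood radius (pixels) used when
#'   suppressing nearby watershed markers.
#' @param scale_um_per_px Optional physical scale, not interpreted.
#' @return An object of class `curvseg_config` (a validated list).
#' @export
pipeline_config <- function(entropy_window = 9L,
                            texture_threshold_mode = c("otsu", "fixed"),
                            texture_threshold = 0.5,
                            min_object_size = 64L,
                            struct_elem_radius = 2L,
                            curvelet_scales = NULL,
                            curvelet_angles_coarse = 16L,
                            box_sizes = NULL,
                            wiener_window = 3L,
                            seed = 1L,
                            hp_gain = 1,
                            hp_source = c("denoised", "raw"),
                            overlay_on = c("enhanced", "entropy"),
                            occupancy = c("ge1", "gt1"),
                            entropy_support_correction = TRUE,
                            watershed_tolerance = 0.1,
                            min_marker_distance = 5L,
                            scale_um_per_px = NA_real_) {
  cfg <- list(
    entropy_window = as.integer(entropy_window),
    texture_threshold_mode = match.arg(texture_threshold_mode),
    texture_threshold = as.numeric(texture_threshold),
    min_object_size = as.integer(min_object_size),
    struct_elem_radius = as.integer(struct_elem_radius),
    curvelet_scales = if (is.null(curvelet_scales)) NULL else as.integer(curvelet_scales),
    curvelet_angles_coarse = as.integer(curvelet_angles_coarse),
    box_sizes = if (is.null(box_sizes)) NULL else as.integer(box_sizes),
    wiener_window = as.integer(wiener_window),
    seed = as.integer(seed),
    hp_gain = as.numeric(hp_gain),
    hp_source = match.arg(hp_source),
    overlay_on = match.arg(overlay_on),
    occupancy = match.arg(occupancy),
    entropy_support_correction = isTRUE(entropy_support_correction),
    watershed_tolerance = as.numeric(watershed_tolerance),
    min_marker_distance = as.integer(min_marker_distance),
    scale_um_per_px = as.numeric(scale_um_per_px)
  )
  validate_config(cfg)
  class(cfg) <- "curvseg_config"
  cfg
}

validate_config <- function(cfg) {
  if (cfg$entropy_window < 3L || cfg$entropy_window %% 2L == 0L)
    stop("entropy_window must be an odd integer >= 3", call. = FALSE)
  if (cfg$wiener_window < 3L || cfg$wiener_window %% 2L == 0L)
    stop("wiener_window must be an odd integer >= 3", call. = FALSE)
  if (!cfg$curvelet_angles_coarse %in% c(8L, 16L, 32L))
    stop("curvelet_angles_coarse must be 8, 16 or 32", call. = FALSE)
  if (!is.null(cfg$curvelet_scales) && cfg$curvelet_scales < 2L)
    stop("curvelet_scales must be >= 2", call. = FALSE)
  if (cfg$min_object_size < 0L) stop("min_object_size must be >= 0", call. = FALSE)
  if (cfg$struct_elem_radius < 1L) stop("struct_elem_radius must be >= 1", call. = FALSE)
  if (cfg$min_marker_distance < 1L) stop("min_marker_distance must be >= 1", call. = FALSE)
  if (!is.null(cfg$box_sizes)) {
    bs <- cfg$box_sizes
    if (any(bs < 2L) || any(diff(bs) <= 0L))
      stop("box_sizes must be strictly increasing integers >= 2", call. = FALSE)
  }
  invisible(cfg)
}

# box_sizes / curvelet_scales resolved against a concrete image shape.
resolve_box_sizes <- function(cfg, shape) {
  if (!is.null(cfg$box_sizes)) {
    if (max(cfg$box_sizes) > min(shape) / 2)
      stop("largest box size exceeds min(H, W)/2", call. = FALSE)
    return(cfg$box_sizes)
  }
  dyadic_box_sizes(shape)
}

resolve_scales <- function(cfg, shape) {
  jmax <- floor(log2(min(shape)))           # need min(H, W) >= 2^J
  j <- if (is.null(cfg$curvelet_scales)) {
    max(4L, as.integer(ceiling(log2(min(shape)))) - 3L)
  } else cfg$curvelet_scales
  as.integer(min(j, jmax))
}

#' Save / load a pipeline configuration as JSON
#'
#' @param config A `curvseg_config`.
#' @param path JSON file path.
#' @return `read_config` returns a `curvseg_config`; `write_config` returns
#'   `path` invisibly.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw[!vapply(raw, is.null, logical(1L))])
}

#' Write per-region statistics to CSV
#'
#' Serializes the `label`, `area_px`, `perimeter_px` and `fractal_dimension`
#' columns of a region-statistics table (as produced by [quantify_all()]).
#' Values round-trip through [read_region_stats()] to at least 6 significant
#' digits.
#'
#' @param stats A data frame with at least the four columns above; an empty
#'   data frame writes a header-only CSV.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_region_stats <- function(stats, path) {
  cols <- c("label", "area_px", "perimeter_px", "fractal_dimension")
  if (nrow(stats) == 0L) {
    out <- data.frame(label = integer(), area_px = integer(),
                      perimeter_px = integer(), fractal_dimension = numeric())
  } else {
    if (!all(cols %in% names(stats)))
      stop("stats must contain columns ", paste(cols, collapse = ", "), call. = FALSE)
    out <- stats[, cols]
    out$fractal_dimension <- signif(out$fractal_dimension, 9L)
  }
  ok <- try(utils::write.csv(out, path, row.names = FALSE, quote = FALSE),
            silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("could not write region stats to ", path, call. = FALSE)
  invisible(path)
}

#' @rdname write_region_stats
#' @export
read_region_stats <- function(path) {
  utils::read.csv(path, colClasses = c(label = "integer", area_px = "integer",
                                       perimeter_px = "integer",
                                       fractal_dimension = "numeric"))
}
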