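#' Adaptive Wiener denoising
#'
#' Pixelwise (local-statistics) Wiener filter: around each pixel a local mean
#' `m` and local variance `v` are computed over a `window x window`
#' neighbourhood (symmetric border padding); the noise power `nu` is estimated
#' as the mean of all local variances; the output is
#' `m + max(v - nu, 0) / max(v, nu) * (x - m)`, clipped to `[0, 1]`.
#' Flat areas (where `v <= nu`) collapse to their local mean while
#' high-variance structure, i.e. edges, is passed through — a least-squares
#' noise suppressor that preserves edges.
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param window Odd window size in pixels (default 3).
#' @return Denoised matrix, same shape, values in `[0, 1]`.
#' @export
wiener_denoise <- function(image, window = 3L) {
  stop_if_not_image(image)
  window <- check_odd_window(window, dim(image))
  m <- box_mean(image, window)
  v <- pmax(box_mean(image * image, window) - m * m, 0)
  nu <- mean(v)
  denom <- pmax(v, nu)
  gain <- ifelse(denom > 0, pmax(v - nu, 0) / denom, 0)
  clamp01(m + gain * (image - m))
}
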