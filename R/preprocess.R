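#' Estimate the noise standard deviation of a gray volume
#'
#' Robust pseudo-residual estimate: the median absolute first difference
#' along x, scaled by `1.4826 / sqrt(2)`, which is insensitive to edges
#' and structures occupying a minority of voxel pairs.
#'
#' @param volume a `tomo_volume` or numeric array.
#' @return estimated noise SD (gray levels).
#' @export
estimate_noise_sd <- function(volume) {
  arr <- if (inherits(volume, "tomo_volume")) volume$data else volume
  d <- dim(arr)
  dx <- arr[-1, , , drop = FALSE] - arr[-d[1], , , drop = FALSE]
  1.4826 * median(abs(dx)) / sqrt(2)
}

#' Non-local means denoising
#'
#' Slice-wise (2D) non-local means with Gaussian patch weighting: each
#' voxel is replaced by a weighted mean of search-window voxels, weighted
#' by the noise-compensated Gaussian-patch distance
#' `w = exp(-max(d2 - 2 * sigma^2, 0) / h^2)`. The output is a convex
#' combination of input values, so the gray range is preserved.
#'
#' @param volume a `tomo_volume` of kind `"gray8"`.
#' @param patch_radius patch half-width in pixels (>= 1).
#' @param search_radius search-window half-width in pixels (>= 1).
#' @param h filtering strength in gray levels, or `"auto"` for
#'   `0.8 x` the estimated noise SD.
#' @param sigma noise SD in gray levels, or `"auto"` to estimate with
#'   [estimate_noise_sd()].
#' @return a denoised `tomo_volume` of kind `"gray8"` (integer gray
#'   levels, rounded half away from zero).
#' @export
nlm_denoise <- function(volume, patch_radius = 2L, search_radius = 5L,
                        h = "auto", sigma = "auto") {
  stopifnot(inherits(volume, "tomo_volume"))
  if (volume$kind != "gray8") stop("`volume` must be a gray8 volume")
  if (patch_radius < 1L || search_radius < 1L) {
    stop("`patch_radius` and `search_radius` must be >= 1")
  }
  if (identical(sigma, "auto")) sigma <- estimate_noise_sd(volume)
  if (identical(h, "auto")) h <- 0.8 * sigma
  if (!is.numeric(h) || h < 0) stop("`h` must be non-negative")
  h <- max(h, 1e-6)
  d <- dim(volume$data)
  out <- cpp_nlm_stack(volume$data, d[1], d[2], d[3],
                       as.integer(patch_radius),
                       as.integer(search_radius),
                       h, max(sigma, 0))
  out <- clamp(round_half_up(out), 0, 255)
  res <- tomo_volume(out, volume$voxel_size_um, "gray8")
  attr(res, "nlm") <- list(patch_radius = patch_radius,
                           search_radius = search_radius,
                           h = h, sigma = sigma)
  res
}
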