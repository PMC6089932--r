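#' Flat-field correction to absorbance
#'
#' Converts raw counts to absorbance via the Beer-Lambert law:
#' `A = -log((projection - dark) / (flat - dark))`, with the transmission
#' ratio clipped to `[1e-6, Inf)` before the logarithm and the result
#' clipped to be non-negative. Clipping events are reported through a
#' warning and recorded in the `clip_count` attribute.
#'
#' @param projection counts array, either `(detector, angles, slices)` or
#'   a single image.
#' @param flat flat-field counts: same shape as one projection
#'   (`detector x slices`) or the full stack.
#' @param dark dark counts, same shape rules as `flat`; default 0.
#' @param geometry optional `acquisition_geometry`; when given, a
#'   `sinogram` object is returned instead of a bare array.
#' @return absorbance array (or `sinogram` when `geometry` is supplied).
#' @export
flat_field_correct <- function(projection, flat, dark = NULL,
                               geometry = NULL) {
  eps <- 1e-6
  if (is.null(dark)) dark <- array(0, dim = dim(flat))
  if (all(flat == 0)) stop("flat field is all zero; cannot normalise")
  denom <- flat - dark
  if (any(denom <= 0)) stop("flat must exceed dark everywhere")
  pd <- dim(projection)
  out <- array(0, dim = pd)
  nclip <- 0L
  if (length(pd) == 3L && length(dim(flat)) == 2L) {
    for (z in seq_len(pd[3])) {
      ratio <- (projection[, , z] - dark[, z]) / denom[, z]
      nclip <- nclip + sum(ratio < eps)
      out[, , z] <- -log(pmax(ratio, eps))
    }
  } else {
    ratio <- (projection - dark) / denom
    nclip <- sum(ratio < eps)
    out <- array(-log(pmax(ratio, eps)), dim = pd)
  }
  out <- pmax(out, 0)
  if (nclip > 0L) {
    warning(sprintf(
      "%d transmission values clipped to %.0e during flat-field correction",
      nclip, eps
    ))
  }
  attr(out, "clip_count") <- nclip
  if (!is.null(geometry)) {
    sino <- new_sinogram(out, geometry, "absorbance")
    return(sino)
  }
  out
}

#' Compose an extended-FOV sinogram from an offset-axis 360-degree scan
#'
#' With the rotation axis shifted toward one detector edge, the views at
#' `theta` and `theta + 180` degrees see complementary halves of the
#' sample. Mirroring the second half-turn about the axis position and
#' joining it to the first composes a 180-degree sinogram on a wider
#' virtual detector of `detector_width + 2 * axis_offset` pixels; the
#' doubly covered band around the axis is blended with a linear ramp
#' (`blend = "ramp"`, default) or split at the axis (`"hard"`).
#'
#' @param sino360 a 360-degree absorbance `sinogram` with an even number
#'   of projections and a positive integer `axis_offset` (for
#'   `axis_offset = 0` only `blend = "hard"` is accepted and returns the
#'   degenerate identity composition; use a plain 180-degree pipeline
#'   instead).
#' @param blend `"ramp"` or `"hard"`.
#' @return an `extended_sinogram` (also a `sinogram`) spanning 180 degrees
#'   with fields `composed_width`, `overlap_width`, `blend`.
#' @export
compose_extended_sinogram <- function(sino360, blend = c("ramp", "hard")) {
  blend <- match.arg(blend)
  stopifnot(inherits(sino360, "sinogram"), sino360$values == "absorbance")
  g <- sino360$geometry
  if (g$angular_range != 360) {
    stop("extended-FOV composition requires a 360-degree scan")
  }
  if (g$n_projections %% 2L != 0L) {
    stop("`n_projections` must be even to pair opposed views")
  }
  off <- g$axis_offset
  if (off != round(off)) stop("`axis_offset` must be an integer (pixels)")
  if (off == 0 && blend == "ramp") {
    stop(paste0(
      "axis_offset is 0: there is nothing to extend; use a plain ",
      "180-degree reconstruction pipeline (or blend = \"hard\" for the ",
      "degenerate identity composition)"
    ))
  }
  W <- g$detector_width
  e <- W / 2 - off          # pixels on the short side of the axis
  C <- as.integer(2 * (W - e))  # composed width = W + 2*off
  na2 <- g$n_projections %/% 2L
  d <- dim(sino360$data)
  nz <- d[3]
  A <- sino360$data[, seq_len(na2), , drop = FALSE]
  B <- sino360$data[, na2 + seq_len(na2), , drop = FALSE]
  Bm <- B[W:1, , , drop = FALSE]  # mirrored about the axis boundary
  out <- array(0, dim = c(C, na2, nz))
  ## composed indices (1-based): A occupies 1..W, mirrored B occupies
  ## (C - W + 1)..C; the overlap band is (C - W + 1)..W, width 2e.
  left_only <- seq_len(C - W)
  right_only <- W + seq_len(C - W)
  ov <- (C - W + 1):W
  nov <- length(ov)
  if (blend == "ramp" && nov > 0) {
    wl <- (nov:1 - 0.5) / nov  # A's weight ramps 1 -> 0 across the band
  } else {
    wl <- as.numeric(ov <= C / 2)  # hard split at the axis
  }
  out[left_only, , ] <- A[left_only, , , drop = FALSE]
  out[right_only, , ] <- Bm[right_only - (C - W), , , drop = FALSE]
  if (nov > 0) {
    out[ov, , ] <- wl * A[ov, , , drop = FALSE] +
      (1 - wl) * Bm[ov - (C - W), , , drop = FALSE]
  }
  geom <- acquisition_geometry(
    detector_width = C, pixel_size_um = g$pixel_size_um,
    n_projections = na2, angular_range = 180, axis_offset = 0L,
    flux = g$flux, seed = g$seed
  )
  sino <- new_sinogram(out, geom, "absorbance")
  sino$composed_width <- C
  sino$overlap_width <- as.integer(2 * e)
  sino$blend <- blend
  class(sino) <- c("extended_sinogram", class(sino))
  sino
}

## frequency response of the Ram-Lak (ramp) filter of length L, from the
## exact band-limited spatial kernel; optional apodisation window
ramp_filter_response <- function(L, filter_name = c("ramlak", "hann")) {
  filter_name <- match.arg(filter_name)
  h <- numeric(L)
  n <- c(0:(L / 2), -(L / 2 - 1):-1)
  h[1] <- 0.25
  odd <- which(n %% 2 != 0)
  h[odd] <- -1 / (pi * n[odd])^2
  H <- Re(stats::fft(h))
  if (filter_name == "hann") {
    f <- n / L  # cycles/sample, |f| <= 0.5
    H <- H * (0.5 + 0.5 * cos(2 * pi * f))
  }
  H
}

#' Filtered back-projection reconstruction
#'
#' Standard slice-by-slice parallel-beam FBP: each sinogram row is
#' convolved with the band-limited ramp (Ram-Lak) kernel via FFT
#' (optionally apodised with a Hann window), then back-projected with
#' linear interpolation and scaled by `pi / n_angles`. The output is an
#' attenuation volume in 1/mm on a `width x width x nz` grid with the
#' detector pixel size as voxel size.
#'
#' @param sino a 180-degree `sinogram` or `extended_sinogram` with at
#'   least 2 angles and a centred axis.
#' @param filter_name `"ramlak"` (default) or `"hann"`.
#' @return a `tomo_volume` of kind `"attenuation"`.
#' @export
fbp_reconstruct <- function(sino, filter_name = c("ramlak", "hann")) {
  filter_name <- match.arg(filter_name)
  stopifnot(inherits(sino, "sinogram"), sino$values == "absorbance")
  g <- sino$geometry
  if (g$angular_range != 180) {
    stop("FBP needs 180-degree data; compose or acquire a 180-degree scan")
  }
  if (g$n_projections < 2L) stop("FBP needs at least 2 angles")
  if (g$axis_offset != 0) {
    stop("FBP expects a centred axis; compose the extended sinogram first")
  }
  d <- dim(sino$data)
  ndet <- d[1]; na <- d[2]; nz <- d[3]
  L <- 2^ceiling(log2(2 * ndet))
  H <- ramp_filter_response(L, filter_name)
  px_mm <- g$pixel_size_um / 1000
  filt <- array(0, dim = d)
  for (z in seq_len(nz)) {
    P <- matrix(0, nrow = L, ncol = na)
    P[seq_len(ndet), ] <- sino$data[, , z]
    Q <- Re(stats::mvfft(stats::mvfft(P) * H, inverse = TRUE)) / L
    filt[, , z] <- Q[seq_len(ndet), ] / px_mm
  }
  ang <- projection_angles(g) * pi / 180
  vol <- cpp_back_project(filt, ndet, na, nz, ang, 0, ndet, ndet)
  vol <- vol * (pi / na)
  tomo_volume(vol, g$pixel_size_um, "attenuation")
}

#' Convert an attenuation volume to 8-bit gray levels
#'
#' Linear mapping of the `[P_low, P_high]` percentile window to
#' `[0, 255]`, clipped and rounded half away from zero. Percentile (not
#' min/max) scaling keeps isolated hot pixels from compressing the useful
#' gray range; segmentation gray thresholds are interpreted on this
#' scale.
#'
#' @param volume a `tomo_volume` of kind `"attenuation"`.
#' @param low_percentile,high_percentile window percentiles (0-100);
#'   defaults 0.5 and 99.5.
#' @return a `tomo_volume` of kind `"gray8"`.
#' @export
to_8bit <- function(volume, low_percentile = 0.5, high_percentile = 99.5) {
  stopifnot(inherits(volume, "tomo_volume"))
  if (high_percentile <= low_percentile) {
    stop("`high_percentile` must exceed `low_percentile`")
  }
  q <- quantile(volume$data, c(low_percentile, high_percentile) / 100,
                names = FALSE)
  if (q[2] <= q[1]) {
    warning("degenerate intensity window (constant volume?); output all 0")
    return(tomo_volume(array(0, dim = dim(volume$data)),
                       volume$voxel_size_um, "gray8"))
  }
  ## stepwise to keep one large temporary alive at a time
  g <- volume$data - q[1]
  g <- g * (255 / (q[2] - q[1]))
  g <- round_half_up(g)
  g <- clamp(g, 0, 255)
  out <- tomo_volume(g, volume$voxel_size_um, "gray8")
  attr(out, "window") <- q
  out
}
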