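#' Parallel-beam acquisition geometry
#'
#' Describes a synchrotron-style parallel-beam scan: detector size, pixel
#' pitch, the uniformly spaced angular grid (endpoint excluded), the
#' rotation-axis position on the detector, and the flat-field photon flux.
#'
#' The rotation axis projects onto the detector at the pixel *boundary*
#' `detector_width / 2 + axis_offset` (pixels; 0 = centred, positive moves
#' the axis toward one edge as in extended field-of-view scanning), so
#' integer offsets keep opposed projections pixel-aligned.
#'
#' @param detector_width detector width in pixels.
#' @param pixel_size_um detector pixel size, micrometres.
#' @param n_projections number of projections (>= 1).
#' @param angular_range total scan range in degrees, 180 or 360.
#' @param axis_offset rotation-axis offset from the detector centre in
#'   pixels; `0 <= axis_offset < detector_width / 2`.
#' @param flux mean flat-field counts per detector pixel.
#' @param seed integer seed for photon-noise simulation.
#' @return an `acquisition_geometry` object.
#' @export
acquisition_geometry <- function(detector_width = 2048L,
                                 pixel_size_um = 0.82,
                                 n_projections = 2048L,
                                 angular_range = 360,
                                 axis_offset = 0L,
                                 flux = 20000,
                                 seed = 1L) {
  detector_width <- as.integer(detector_width)
  n_projections <- as.integer(n_projections)
  if (detector_width < 1L) stop("`detector_width` must be positive")
  if (pixel_size_um <= 0) stop("`pixel_size_um` must be positive")
  if (n_projections < 1L) stop("`n_projections` must be >= 1")
  if (!angular_range %in% c(180, 360)) {
    stop("`angular_range` must be 180 or 360 degrees")
  }
  if (axis_offset < 0 || axis_offset >= detector_width / 2) {
    stop("`axis_offset` must satisfy 0 <= axis_offset < detector_width/2")
  }
  if (flux <= 0) stop("`flux` must be positive")
  structure(
    list(
      detector_width = detector_width,
      pixel_size_um = pixel_size_um,
      n_projections = n_projections,
      angular_range = angular_range,
      axis_offset = axis_offset,
      flux = flux,
      seed = as.integer(seed)
    ),
    class = "acquisition_geometry"
  )
}

#' Projection angles of a geometry
#'
#' Uniformly spaced on `[0, angular_range)` with the endpoint excluded, so
#' a 360-degree scan never duplicates the 0-degree view.
#'
#' @param geometry an `acquisition_geometry`.
#' @return angles in degrees.
#' @export
projection_angles <- function(geometry) {
  geometry$angular_range * (seq_len(geometry$n_projections) - 1L) /
    geometry$n_projections
}

#' Field of view of a detector
#'
#' @param n_pixels detector width in pixels.
#' @param pixel_size_um pixel size in micrometres.
#' @return a list with `mm` (exact product, millimetres) and `display`
#'   (rounded to one decimal, the conventional quoted value).
#' @examples
#' field_of_view_mm(2048, 0.82)$display  # 1.7
#' field_of_view_mm(2048, 4.11)$display  # 8.4
#' @export
field_of_view_mm <- function(n_pixels, pixel_size_um) {
  if (n_pixels <= 0 || pixel_size_um <= 0) {
    stop("`n_pixels` and `pixel_size_um` must be positive")
  }
  mm <- n_pixels * pixel_size_um / 1000
  list(mm = mm, display = round(mm, 1))
}

#' Minimum projections under the Crowther criterion
#'
#' The minimum number of uniformly spaced projections over 180 degrees to
#' recover an object `width` resolution elements wide without angular
#' undersampling artefacts: `ceiling(pi * width / 2)`. A 2048-pixel object
#' requires 3217 projections, more than the 2048 actually collected in
#' typical beam-time-limited scans.
#'
#' @param object_width_pixels object width in resolution elements (>= 1).
#' @return required projection count (integer).
#' @export
crowther_required_projections <- function(object_width_pixels) {
  if (object_width_pixels < 1) stop("`object_width_pixels` must be >= 1")
  as.integer(ceiling(pi * object_width_pixels / 2))
}

#' Sinogram container
#' @keywords internal
new_sinogram <- function(data, geometry, values = c("absorbance", "counts")) {
  values <- match.arg(values)
  structure(
    list(data = data, geometry = geometry, values = values),
    class = "sinogram"
  )
}

#' @export
print.sinogram <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<sinogram> %d detector px x %d angles (%g deg) x %d slices, %s\n",
    d[1], d[2], d[3], x$geometry$angular_range, x$values
  ))
  invisible(x)
}

#' Forward-project a volume into a sinogram
#'
#' Parallel-beam line integrals of the attenuation volume along rays
#' perpendicular to the detector, computed by a pixel-driven projector
#' with linear detector interpolation: it conserves the per-slice mass at
#' every angle and is the exact adjoint of the back-projector used in
#' reconstruction. Angle 0 projects along `+y`; angles increase
#' counterclockwise; output is in absorbance units (dimensionless).
#'
#' @param volume a `tomo_volume` of kind `"attenuation"` (1/mm); its voxel
#'   size must equal the detector pixel size.
#' @param geometry an `acquisition_geometry`.
#' @return a `sinogram` with data dimensions
#'   `(detector_width, n_projections, nz)`.
#' @export
forward_project <- function(volume, geometry) {
  stopifnot(inherits(volume, "tomo_volume"),
            inherits(geometry, "acquisition_geometry"))
  if (volume$kind != "attenuation") {
    stop("`volume` must be an attenuation volume")
  }
  if (any(volume$data < 0)) stop("attenuation must be non-negative")
  if (abs(volume$voxel_size_um - geometry$pixel_size_um) >
      1e-9 * geometry$pixel_size_um) {
    stop("voxel size and detector pixel size must match")
  }
  d <- dim(volume$data)
  ## lateral support check: every nonzero voxel must stay on the detector
  ## at all angles (radius from the rotation axis vs. covered half-width)
  support2d <- apply(volume$data != 0, c(1, 2), any)
  if (any(support2d)) {
    ij <- which(support2d, arr.ind = TRUE)
    r_vox <- sqrt((ij[, 1] - 0.5 - d[1] / 2)^2 + (ij[, 2] - 0.5 - d[2] / 2)^2)
    max_r <- max(r_vox)
    covered <- geometry$detector_width / 2 + geometry$axis_offset
    if (max_r > covered + 0.5) {
      stop(sprintf(
        "volume support (radius %.1f px) exceeds the reconstructible FOV; a detector of at least %d pixels is required",
        max_r, as.integer(ceiling(2 * max_r))
      ))
    }
  }
  ang <- projection_angles(geometry) * pi / 180
  sino <- cpp_forward_project(
    volume$data, d[1], d[2], d[3],
    geometry$detector_width, ang,
    geometry$axis_offset, geometry$pixel_size_um / 1000
  )
  new_sinogram(sino, geometry, "absorbance")
}

#' Simulate photon counts, flat fields and darks
#'
#' Expected projection counts follow the Beer-Lambert law,
#' `flux * exp(-absorbance)`, with Poisson photon noise; the flat field is
#' a Poisson realisation of the bare flux and darks are zero.
#'
#' @param sino an absorbance `sinogram` from [forward_project()].
#' @param geometry geometry (defaults to the sinogram's own).
#' @param noise simulate Poisson noise (`FALSE` returns exact expected
#'   counts, the infinite-flux limit).
#' @param rng_seed integer seed; identical seeds give identical noise.
#' @return list with `projections` (detector x angles x slices), `flat`
#'   and `dark` (detector x slices), and `geometry`.
#' @export
simulate_counts <- function(sino, geometry = sino$geometry, noise = TRUE,
                            rng_seed = geometry$seed) {
  stopifnot(inherits(sino, "sinogram"), sino$values == "absorbance")
  expected <- geometry$flux * exp(-sino$data)
  d <- dim(sino$data)
  if (noise) {
    with_seed(rng_seed, {
      proj <- array(rpois(length(expected), expected), dim = d)
      flat <- array(rpois(d[1] * d[3], geometry$flux), dim = c(d[1], d[3]))
      list(projections = proj, flat = flat,
           dark = array(0, dim = c(d[1], d[3])), geometry = geometry)
    })
  } else {
    list(projections = expected,
         flat = array(geometry$flux, dim = c(d[1], d[3])),
         dark = array(0, dim = c(d[1], d[3])), geometry = geometry)
  }
}

#' Apply a source-size (penumbra) PSF to projections
#'
#' Optional anisotropic Gaussian blur emulating the finite source size of
#' a bending-magnet beamline, which limits resolution to about 3 um
#' horizontally (across the detector) and 1 um vertically (along the
#' rotation axis).
#'
#' @param sino an absorbance `sinogram`.
#' @param sigma_h_um horizontal (detector-axis) sigma, micrometres.
#' @param sigma_v_um vertical (slice-axis) sigma, micrometres.
#' @return the blurred `sinogram`.
#' @export
apply_projection_psf <- function(sino, sigma_h_um = 3, sigma_v_um = 1) {
  stopifnot(inherits(sino, "sinogram"))
  px <- sino$geometry$pixel_size_um
  blur1d <- function(arr, sigma_px, axis) {
    if (sigma_px <= 0) return(arr)
    r <- max(1L, ceiling(3 * sigma_px))
    k <- exp(-0.5 * ((-r:r) / sigma_px)^2)
    k <- k / sum(k)
    d <- dim(arr)
    out <- array(0, dim = d)
    ## edge replication along the blurred axis
    for (shift in -r:r) {
      w <- k[shift + r + 1]
      if (axis == 1L) {
        src <- clamp(seq_len(d[1]) + shift, 1L, d[1])
        out <- out + w * arr[src, , , drop = FALSE]
      } else {
        src <- clamp(seq_len(d[3]) + shift, 1L, d[3])
        out <- out + w * arr[, , src, drop = FALSE]
      }
    }
    out
  }
  data <- blur1d(sino$data, sigma_h_um / px, 1L)
  data <- blur1d(data, sigma_v_um / px, 3L)
  sino$data <- data
  sino
}
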