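#' 3D image volume
#'
#' A `tomo_volume` wraps a 3D array with an isotropic voxel size and a value
#' semantic: `"attenuation"` (linear attenuation coefficient, 1/mm),
#' `"gray8"` (8-bit gray levels 0..255) or `"label"` (non-negative integer
#' object labels, 0 = background).
#'
#' Coordinate convention: voxels are addressed by 0-based indices
#' `(x, y, z)` with `x` varying fastest in storage; the centre of voxel
#' `(i, j, k)` sits at physical position `(i + 0.5, j + 0.5, k + 0.5) *
#' voxel_size` micrometres, and `z` is the rotation axis.
#'
#' @param data numeric 3D array.
#' @param voxel_size_um isotropic voxel edge length in micrometres.
#' @param kind one of `"attenuation"`, `"gray8"`, `"label"`.
#' @return a `tomo_volume` object.
#' @export
tomo_volume <- function(data, voxel_size_um,
                        kind = c("attenuation", "gray8", "label")) {
  kind <- match.arg(kind)
  if (length(dim(data)) != 3L) {
    stop("`data` must be a 3D array")
  }
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1L ||
      voxel_size_um <= 0) {
    stop("`voxel_size_um` must be a single positive number")
  }
  if (kind == "gray8") {
    rng <- range(data)
    if (rng[1] < 0 || rng[2] > 255) {
      stop("gray8 volumes must have values in [0, 255]")
    }
  }
  if (kind == "label" && any(data < 0)) {
    stop("label volumes must be non-negative")
  }
  structure(
    list(data = data, voxel_size_um = voxel_size_um, kind = kind),
    class = "tomo_volume"
  )
}

#' @export
print.tomo_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<tomo_volume> %d x %d x %d voxels, %.3g um/voxel, kind = %s\n",
    d[1], d[2], d[3], x$voxel_size_um, x$kind
  ))
  cat(sprintf("  value range: [%.4g, %.4g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' Voxel volume in cubic millimetres
#' @param volume a `tomo_volume` or a voxel size in micrometres.
#' @return voxel volume in mm^3.
#' @export
voxel_volume_mm3 <- function(volume) {
  vs <- if (inherits(volume, "tomo_volume")) volume$voxel_size_um else volume
  (vs / 1000)^3
}

#' Write a volume as a multi-page TIFF stack with a sidecar metadata file
#'
#' One TIFF page per z-slice. `gray8` and `label` volumes are written as
#' 8-/16-bit integer pages, attenuation volumes as 32-bit float. A YAML
#' sidecar (`<path>.meta.yaml`) records voxel size, kind and the coordinate
#' convention so a volume round-trips losslessly.
#'
#' @param volume a `tomo_volume`.
#' @param path output TIFF file path.
#' @param extra named list of additional metadata (e.g. seed, spec echo).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, extra = list()) {
  stopifnot(inherits(volume, "tomo_volume"))
  d <- dim(volume$data)
  pages <- vector("list", d[3])
  offset <- 0
  if (volume$kind == "gray8") {
    bps <- 8L
    scale <- 255
  } else if (volume$kind == "label") {
    if (max(volume$data) > 65535) stop("label volume exceeds 16-bit range")
    bps <- 16L
    scale <- 65535
  } else {
    ## float pages must live in [0, 1]; record the affine map in the
    ## sidecar so values restore exactly (to float32 precision)
    bps <- 32L
    rng <- range(volume$data)
    offset <- rng[1]
    scale <- max(rng[2] - rng[1], 1e-30)
  }
  for (z in seq_len(d[3])) {
    ## tiff expects matrices in row = y orientation and [0,1] values
    page <- (t(volume$data[, , z]) - offset) / scale
    pages[[z]] <- page
  }
  tiff::writeTIFF(pages, path, bits.per.sample = bps,
                  compression = "none",
                  reduce = FALSE)
  meta <- c(list(
    voxel_size_um = volume$voxel_size_um,
    kind = volume$kind,
    shape_xyz = as.integer(d),
    axis_order = "z is rotation axis; voxel-centred 0-based indices",
    value_scale = scale,
    value_offset = offset
  ), extra)
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  invisible(path)
}

#' Read a volume written by [write_volume()]
#'
#' @param path TIFF file path (with `<path>.meta.yaml` alongside).
#' @return a `tomo_volume`.
#' @export
read_volume <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".meta.yaml"))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  d <- c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages))
  offset <- meta$value_offset
  if (is.null(offset)) offset <- 0
  arr <- array(0, dim = d)
  for (z in seq_along(pages)) {
    arr[, , z] <- t(pages[[z]]) * meta$value_scale + offset
  }
  if (meta$kind != "attenuation") arr <- round(arr)
  tomo_volume(arr, meta$voxel_size_um, meta$kind)
}
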