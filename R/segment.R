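#' Segmentation parameters
#'
#' Gray-level ranges and morphology settings for the three segmentation
#' recipes, defaulting to the values used for 8-bit Golgi-Cox micro-CT
#' reconstructions: watershed brain/background seeds at 130-255 / 0-126,
#' cell bodies thresholded at 142-255 with a dilation step and a
#' "larger than 9 um equivalent diameter" size filter, and neurons at
#' 139-255 with morphological closing and island removal. The nominal
#' upper gray bound of 256 quoted for 8-bit data is read as 255.
#'
#' @param brain_seed_range gray range seeding the tissue marker.
#' @param background_seed_range gray range seeding the background marker;
#'   must not overlap `brain_seed_range`.
#' @param cellbody_threshold_range gray range selecting bright somata.
#' @param neuron_threshold_range gray range selecting neuron voxels.
#' @param dilation_radius,erosion_radius structuring-element (digital
#'   ball) radii in voxels.
#' @param min_equiv_diameter size filter: keep objects with equivalent
#'   spherical diameter strictly larger than this (micrometres). The
#'   companion value 10 um quoted in running text is available by setting
#'   this parameter; the tabulated 9 um is the default.
#' @param min_island_voxels remove neuron components smaller than this.
#' @param connectivity voxel connectivity: 6, 18 or 26.
#' @return a `segmentation_params` object.
#' @export
segmentation_params <- function(brain_seed_range = c(130, 255),
                                background_seed_range = c(0, 126),
                                cellbody_threshold_range = c(142, 255),
                                neuron_threshold_range = c(139, 255),
                                dilation_radius = 1,
                                erosion_radius = 1,
                                min_equiv_diameter = 9,
                                min_island_voxels = 10L,
                                connectivity = 26L) {
  ranges <- list(brain_seed_range = brain_seed_range,
                 background_seed_range = background_seed_range,
                 cellbody_threshold_range = cellbody_threshold_range,
                 neuron_threshold_range = neuron_threshold_range)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2L || r[1] > r[2] || r[1] < 0 || r[2] > 255) {
      stop(sprintf("`%s` must be (lo, hi) within [0, 255]", nm))
    }
  }
  if (brain_seed_range[1] <= background_seed_range[2] &&
      background_seed_range[1] <= brain_seed_range[2]) {
    stop("brain and background seed ranges must be disjoint")
  }
  if (min_equiv_diameter <= 0) stop("`min_equiv_diameter` must be positive")
  if (!connectivity %in% c(6L, 18L, 26L)) {
    stop("`connectivity` must be 6, 18 or 26")
  }
  structure(
    c(ranges, list(
      dilation_radius = dilation_radius,
      erosion_radius = erosion_radius,
      min_equiv_diameter = min_equiv_diameter,
      min_island_voxels = as.integer(min_island_voxels),
      connectivity = as.integer(connectivity)
    )),
    class = "segmentation_params"
  )
}

as_mask_array <- function(x) {
  if (inherits(x, "tomo_volume")) x <- x$data
  if (!is.logical(x)) x <- x != 0
  x
}

#' Label connected components of a binary mask
#'
#' Deterministic labelling: components are numbered by the raster
#' (column-major) order of their first voxel.
#'
#' @param mask logical 3D array or binary `tomo_volume`.
#' @param connectivity 6, 18 or 26.
#' @param voxel_size_um voxel size of the returned label volume (taken
#'   from `mask` when it is a `tomo_volume`).
#' @return a `tomo_volume` of kind `"label"` with attribute
#'   `n_components`.
#' @export
label_components <- function(mask, connectivity = 26L, voxel_size_um = 1) {
  if (inherits(mask, "tomo_volume")) voxel_size_um <- mask$voxel_size_um
  m <- as_mask_array(mask)
  d <- dim(m)
  lab <- cpp_label_components(m, d[1], d[2], d[3], as.integer(connectivity))
  n <- attr(lab, "n_components")
  out <- tomo_volume(lab, voxel_size_um, "label")
  attr(out, "n_components") <- n
  out
}

## gradient magnitude by central differences (edge replication)
gradient_magnitude <- function(arr) {
  d <- dim(arr)
  shift <- function(a, k, axis) {
    idx <- clamp(seq_len(d[axis]) + k, 1L, d[axis])
    if (axis == 1L) a[idx, , , drop = FALSE]
    else if (axis == 2L) a[, idx, , drop = FALSE]
    else a[, , idx, drop = FALSE]
  }
  ## accumulate axis by axis to cap peak memory on large volumes
  g <- shift(arr, 1L, 1L) - shift(arr, -1L, 1L)
  acc <- g * g
  g <- shift(arr, 1L, 2L) - shift(arr, -1L, 2L)
  acc <- acc + g * g
  g <- shift(arr, 1L, 3L) - shift(arr, -1L, 3L)
  acc <- acc + g * g
  rm(g)
  sqrt(acc) / 2
}

#' Whole-tissue (brain) mask by seeded watershed
#'
#' Seeds are created by gray-level thresholding (tissue seeds and
#' background seeds), then a marker-based watershed floods the gradient
#' magnitude of the volume. The largest tissue component is retained and
#' interior holes are filled, yielding a binary tissue mask.
#'
#' @param volume a `tomo_volume` of kind `"gray8"` (ideally denoised).
#' @param params a `segmentation_params`.
#' @return a binary `tomo_volume` of kind `"label"` (1 = tissue).
#' @export
brain_mask <- function(volume, params = segmentation_params()) {
  stopifnot(inherits(volume, "tomo_volume"),
            inherits(params, "segmentation_params"))
  if (volume$kind != "gray8") stop("`volume` must be gray8")
  arr <- volume$data
  d <- dim(arr)
  br <- params$brain_seed_range
  bg <- params$background_seed_range
  brain_seed <- arr >= br[1] & arr <= br[2]
  if (!any(brain_seed)) {
    stop(sprintf("no brain seeds found in gray range [%g, %g]",
                 br[1], br[2]))
  }
  back_seed <- arr >= bg[1] & arr <= bg[2]
  markers <- array(0L, dim = d)
  markers[back_seed] <- 2L
  markers[brain_seed] <- 1L  # brain wins where ranges would overlap
  relief <- gradient_magnitude(arr)
  lab <- cpp_marker_watershed(relief, markers, d[1], d[2], d[3])
  mask <- lab == 1L
  ## keep largest tissue component
  comp <- cpp_label_components(mask, d[1], d[2], d[3], 6L)
  ncomp <- attr(comp, "n_components")
  if (ncomp > 1L) {
    sizes <- tabulate(comp[comp > 0L], nbins = ncomp)
    mask <- comp == which.max(sizes)
  }
  ## fill interior holes: background components not touching the border
  hole <- cpp_label_components(!mask, d[1], d[2], d[3], 6L)
  nh <- attr(hole, "n_components")
  if (nh > 0L) {
    border_labels <- unique(c(
      hole[1, , ], hole[d[1], , ], hole[, 1, ], hole[, d[2], ],
      hole[, , 1], hole[, , d[3]]
    ))
    interior <- setdiff(seq_len(nh), border_labels)
    if (length(interior) > 0L) mask[hole %in% interior] <- TRUE
  }
  out <- tomo_volume(array(as.integer(mask), dim = d),
                     volume$voxel_size_um, "label")
  out
}

## measure labelled objects on a set of voxel indices
measure_cells <- function(lab_values, idx, dims, voxel_size_um) {
  if (length(idx) == 0L) {
    return(empty_cell_table(voxel_size_um))
  }
  labs <- sort(unique(lab_values))
  xyz <- index_to_xyz(idx, dims)
  cx <- rowsum(xyz[, 1] + 0.5, lab_values)
  cy <- rowsum(xyz[, 2] + 0.5, lab_values)
  cz <- rowsum(xyz[, 3] + 0.5, lab_values)
  n <- as.vector(rowsum(rep(1, length(idx)), lab_values))
  vox3 <- voxel_size_um^3
  tab <- data.frame(
    label = labs,
    centroid_x_um = as.vector(cx) / n * voxel_size_um,
    centroid_y_um = as.vector(cy) / n * voxel_size_um,
    centroid_z_um = as.vector(cz) / n * voxel_size_um,
    n_voxels = as.integer(n),
    equiv_diameter_um = (6 * n * vox3 / pi)^(1 / 3)
  )
  tab <- tab[order(tab$label), , drop = FALSE]
  tab$label <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  attr(tab, "voxel_size_um") <- voxel_size_um
  class(tab) <- c("cell_table", "data.frame")
  tab
}

empty_cell_table <- function(voxel_size_um) {
  tab <- data.frame(label = integer(0), centroid_x_um = numeric(0),
                    centroid_y_um = numeric(0), centroid_z_um = numeric(0),
                    n_voxels = integer(0), equiv_diameter_um = numeric(0))
  attr(tab, "voxel_size_um") <- voxel_size_um
  class(tab) <- c("cell_table", "data.frame")
  tab
}

#' Segment cell bodies (bright spots)
#'
#' Thresholds the gray volume at the cell-body range, dilates with a
#' digital ball to consolidate fragmented somata, and labels connected
#' components. Object measurements (centroid, voxel count, equivalent
#' spherical diameter) are taken on the pre-dilation voxels of each
#' component, so dilation merges and selects but never inflates sizes.
#'
#' @param volume a denoised `tomo_volume` of kind `"gray8"`.
#' @param params a `segmentation_params`.
#' @return list with `labels` (a label `tomo_volume` on the pre-dilation
#'   voxels) and `cells` (a `cell_table` sorted by label).
#' @export
segment_cell_bodies <- function(volume, params = segmentation_params()) {
  stopifnot(inherits(volume, "tomo_volume"),
            inherits(params, "segmentation_params"))
  if (volume$kind != "gray8") stop("`volume` must be gray8")
  d <- dim(volume$data)
  thr <- params$cellbody_threshold_range
  bin <- volume$data >= thr[1] & volume$data <= thr[2]
  if (!any(bin)) {
    lab <- tomo_volume(array(0L, dim = d), volume$voxel_size_um, "label")
    return(list(labels = lab, cells = empty_cell_table(volume$voxel_size_um)))
  }
  dil <- cpp_morph_ball(bin, d[1], d[2], d[3], params$dilation_radius, TRUE)
  comp <- cpp_label_components(dil, d[1], d[2], d[3], params$connectivity)
  idx <- which(bin)
  lab_values <- comp[idx]
  cells <- measure_cells(lab_values, idx, d, volume$voxel_size_um)
  ## relabel the volume contiguously to match the table
  lab <- array(0L, dim = d)
  lab[idx] <- match(lab_values, sort(unique(lab_values)))
  list(labels = tomo_volume(lab, volume$voxel_size_um, "label"),
       cells = cells)
}

#' Filter a cell table by equivalent diameter
#'
#' Keeps objects with equivalent spherical diameter strictly larger than
#' `min_equiv_diameter` (the "larger than 9 um in diameter" counting
#' rule); row order is preserved.
#'
#' @param cells a `cell_table`.
#' @param min_equiv_diameter minimum diameter, micrometres.
#' @return the filtered `cell_table`.
#' @export
filter_by_diameter <- function(cells, min_equiv_diameter = 9) {
  stopifnot(inherits(cells, "cell_table"))
  out <- cells[cells$equiv_diameter_um > min_equiv_diameter, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "voxel_size_um") <- attr(cells, "voxel_size_um")
  class(out) <- c("cell_table", "data.frame")
  out
}

#' Segment neurons (somata plus neurites)
#'
#' Threshold at the neuron gray range, morphological closing (dilation
#' then erosion) to bridge thin neurites broken by noise, connected
#' components, and removal of spurious small islands. If `seed_points`
#' are given (a programmatic stand-in for interactive brush selection),
#' only components containing a seed are kept.
#'
#' @param volume a denoised `tomo_volume` of kind `"gray8"`.
#' @param params a `segmentation_params`.
#' @param seed_points optional matrix of points (rows of x, y, z in
#'   micrometres); points outside the volume raise an error.
#' @return a `tomo_volume` of kind `"label"` with attribute
#'   `n_components`.
#' @export
segment_neurons <- function(volume, params = segmentation_params(),
                            seed_points = NULL) {
  stopifnot(inherits(volume, "tomo_volume"),
            inherits(params, "segmentation_params"))
  if (volume$kind != "gray8") stop("`volume` must be gray8")
  d <- dim(volume$data)
  vs <- volume$voxel_size_um
  thr <- params$neuron_threshold_range
  bin <- volume$data >= thr[1] & volume$data <= thr[2]
  closed <- cpp_morph_ball(bin, d[1], d[2], d[3], params$dilation_radius,
                           TRUE)
  closed <- cpp_morph_ball(closed, d[1], d[2], d[3], params$erosion_radius,
                           FALSE)
  comp <- cpp_label_components(closed, d[1], d[2], d[3],
                               params$connectivity)
  ncomp <- attr(comp, "n_components")
  keep <- rep(TRUE, ncomp)
  if (ncomp > 0L) {
    sizes <- tabulate(comp[comp > 0L], nbins = ncomp)
    keep <- sizes >= params$min_island_voxels
  }
  if (!is.null(seed_points)) {
    seed_points <- matrix(seed_points, ncol = 3)
    vox <- floor(seed_points / vs)
    bad <- apply(vox, 1, function(v) any(v < 0) || any(v >= d))
    if (any(bad)) {
      stop(sprintf("seed point(s) outside the volume: %s",
                   paste(apply(seed_points[bad, , drop = FALSE], 1,
                               function(p) sprintf("(%g, %g, %g) um",
                                                   p[1], p[2], p[3])),
                         collapse = "; ")))
    }
    seed_idx <- xyz_to_index(vox[, 1], vox[, 2], vox[, 3], d)
    seeded <- unique(comp[seed_idx])
    seeded <- seeded[seeded > 0L]
    keep <- keep & seq_len(ncomp) %in% seeded
  }
  lab <- array(0L, dim = d)
  sel <- comp > 0L & keep[pmax(comp, 1L)]
  old <- comp[sel]
  lab[sel] <- match(old, sort(unique(old)))
  out <- tomo_volume(lab, vs, "label")
  attr(out, "n_components") <- length(unique(old))
  out
}

#' Write a cell table as tab-separated text
#' @param cells a `cell_table`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(cells, path) {
  write.table(as.data.frame(cells), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
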