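#' Published stained-cell density presets
#'
#' Group means and standard deviations (cells/mm^3, n = 5 animals per
#' group) for Golgi-Cox-impregnated cell densities in frontal cortex and
#' hippocampus of control versus pilocarpine status-epilepticus (SE) mice.
#' These are the densities the phantom generator realises by default.
#'
#' @return a data.frame with columns `structure`, `condition`,
#'   `density_mean`, `density_sd`, `n`.
#' @export
golgi_density_presets <- function() {
  data.frame(
    structure = c("cortex", "cortex", "hippocampus", "hippocampus"),
    condition = c("control", "SE", "control", "SE"),
    density_mean = c(31.08, 27.32, 38.51, 19.32),
    density_sd = c(0.5678, 0.9050, 5.5, 1.6),
    n = 5L
  )
}

#' Phantom specification
#'
#' Describes a synthetic Golgi-Cox-stained tissue volume: grid geometry,
#' the tissue region, the stained-cell density to realise, soma and
#' neurite morphology ranges, and the attenuation coefficients of the
#' three materials.
#'
#' Note that the densities are densities of *stained* cells: Golgi-Cox
#' impregnation labels only a small fraction (of the order of 3-10%) of
#' neurons, and the phantom realises that sparse stained population
#' directly rather than modelling the far denser unstained tissue.
#' `labeling_fraction` records the assumed impregnation fraction as
#' metadata.
#'
#' @param shape integer vector of 3 grid sizes `(nx, ny, nz)`; `z` is the
#'   rotation axis.
#' @param voxel_size_um isotropic voxel size in micrometres.
#' @param tissue_mask `"ellipsoid"` (an ellipsoid inscribed in the grid,
#'   semi-axes 0.48 of each extent, emulating a dissected tissue block) or
#'   `"full"` (tissue fills the grid).
#' @param density_mean target stained-cell density, cells/mm^3.
#' @param density_sd_between between-replicate density spread, cells/mm^3.
#' @param labeling_fraction assumed stained fraction of all neurons,
#'   in `[0, 1]`; metadata only (see Details).
#' @param soma_diameter_range `(min, max)` soma diameter, micrometres.
#' @param neurite_count_range `(min, max)` neurites per cell (integers).
#' @param neurite_radius_range `(min, max)` neurite radius, micrometres;
#'   the defaults straddle the voxel size so thin neurites exercise the
#'   resolution limit.
#' @param neurite_length_range `(min, max)` neurite length, micrometres.
#' @param attenuation_background,attenuation_tissue,attenuation_stain
#'   linear attenuation coefficients, 1/mm, for embedding medium, tissue
#'   and mercury stain; must be strictly increasing.
#' @param condition replicate condition label, `"control"` or `"SE"`.
#' @param seed default RNG seed recorded with the spec.
#' @return a `phantom_spec` object.
#' @export
phantom_spec <- function(shape = c(256L, 256L, 128L),
                         voxel_size_um = 4.11,
                         tissue_mask = c("ellipsoid", "full"),
                         density_mean = 31.08,
                         density_sd_between = 0.5678,
                         labeling_fraction = 0.06,
                         soma_diameter_range = c(10, 25),
                         neurite_count_range = c(2L, 5L),
                         neurite_radius_range = c(0.5, 2),
                         neurite_length_range = c(20, 120),
                         attenuation_background = 0.05,
                         attenuation_tissue = 0.5,
                         attenuation_stain = 5.0,
                         condition = c("control", "SE"),
                         seed = 1L) {
  tissue_mask <- match.arg(tissue_mask)
  condition <- match.arg(condition)
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) {
    stop("`shape` must be 3 positive integers")
  }
  if (voxel_size_um <= 0) stop("`voxel_size_um` must be positive")
  if (density_mean < 0) stop("`density_mean` must be non-negative")
  if (density_sd_between < 0) stop("`density_sd_between` must be >= 0")
  if (labeling_fraction < 0 || labeling_fraction > 1) {
    stop("`labeling_fraction` must be in [0, 1]")
  }
  if (soma_diameter_range[1] <= 2 * voxel_size_um) {
    stop(sprintf(
      "somata must be resolvable: soma_diameter_range min (%.3g um) must exceed 2 x voxel_size (%.3g um)",
      soma_diameter_range[1], 2 * voxel_size_um
    ))
  }
  if (diff(soma_diameter_range) < 0 || diff(neurite_count_range) < 0 ||
      diff(neurite_radius_range) < 0 || diff(neurite_length_range) < 0) {
    stop("range parameters must be (min, max) with min <= max")
  }
  if (!(attenuation_stain > attenuation_tissue &&
        attenuation_tissue > attenuation_background)) {
    stop("attenuations must satisfy stain > tissue > background")
  }
  structure(
    list(
      shape = shape,
      voxel_size_um = voxel_size_um,
      tissue_mask = tissue_mask,
      density_mean = density_mean,
      density_sd_between = density_sd_between,
      labeling_fraction = labeling_fraction,
      soma_diameter_range = as.numeric(soma_diameter_range),
      neurite_count_range = as.integer(neurite_count_range),
      neurite_radius_range = as.numeric(neurite_radius_range),
      neurite_length_range = as.numeric(neurite_length_range),
      attenuation_background = attenuation_background,
      attenuation_tissue = attenuation_tissue,
      attenuation_stain = attenuation_stain,
      condition = condition,
      seed = as.integer(seed)
    ),
    class = "phantom_spec"
  )
}

## semi-axes of the ellipsoidal tissue block, micrometres
ellipsoid_semi_axes_um <- function(spec) {
  0.48 * spec$shape * spec$voxel_size_um
}

## single-slot cache: replicate generation rebuilds the same mask many
## times; the mask depends only on shape, voxel size and mask type
.mask_cache <- new.env(parent = emptyenv())

#' Tissue mask of a phantom spec
#'
#' @param spec a `phantom_spec`.
#' @return a logical 3D array, `TRUE` inside tissue.
#' @export
tissue_mask_array <- function(spec) {
  d <- spec$shape
  if (spec$tissue_mask == "full") {
    return(array(TRUE, dim = d))
  }
  key <- paste(c(d, spec$voxel_size_um, spec$tissue_mask), collapse = "|")
  if (identical(.mask_cache$key, key)) {
    return(.mask_cache$mask)
  }
  vs <- spec$voxel_size_um
  ctr <- d * vs / 2
  ax <- ellipsoid_semi_axes_um(spec)
  fx <- (((seq_len(d[1]) - 0.5) * vs - ctr[1]) / ax[1])^2
  fy <- (((seq_len(d[2]) - 0.5) * vs - ctr[2]) / ax[2])^2
  fz <- (((seq_len(d[3]) - 0.5) * vs - ctr[3]) / ax[3])^2
  xy <- outer(fx, fy, "+")
  mask <- array(FALSE, dim = d)
  for (z in seq_len(d[3])) {
    mask[, , z] <- xy + fz[z] <= 1
  }
  .mask_cache$key <- key
  .mask_cache$mask <- mask
  mask
}

#' Tissue volume of a phantom spec in mm^3
#'
#' Counts tissue-mask voxels, so the volume is exactly the reference
#' volume later used for mask-based density computation.
#'
#' @param spec a `phantom_spec`.
#' @return tissue volume, mm^3.
#' @export
tissue_volume_mm3 <- function(spec) {
  if (spec$tissue_mask == "full") {
    return(prod(spec$shape) * voxel_volume_mm3(spec$voxel_size_um))
  }
  sum(tissue_mask_array(spec)) * voxel_volume_mm3(spec$voxel_size_um)
}

## continuous-coordinate inside-tissue test with a margin (um) so somata
## fit entirely inside the tissue block
point_in_tissue <- function(p, spec, margin_um) {
  ext <- spec$shape * spec$voxel_size_um
  if (spec$tissue_mask == "full") {
    return(all(p >= margin_um) && all(p <= ext - margin_um))
  }
  ax <- ellipsoid_semi_axes_um(spec) - margin_um
  if (any(ax <= 0)) return(FALSE)
  sum(((p - ext / 2) / ax)^2) <= 1
}

## linear voxel indices whose centres lie within radius r_um of center_um
sphere_voxel_indices <- function(center_um, r_um, dims, vs) {
  lo <- pmax(1L, as.integer(floor((center_um - r_um) / vs + 0.5)))
  hi <- pmin(dims, as.integer(ceiling((center_um + r_um) / vs + 0.5)))
  if (any(lo > hi)) return(integer(0))
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  dx2 <- ((xs - 0.5) * vs - center_um[1])^2
  dy2 <- ((ys - 0.5) * vs - center_um[2])^2
  dz2 <- ((zs - 0.5) * vs - center_um[3])^2
  keep <- outer(outer(dx2, dy2, "+"), dz2, "+") <= r_um^2
  if (!any(keep)) return(integer(0))
  grid <- as.matrix(expand.grid(x = xs - 1L, y = ys - 1L, z = zs - 1L))
  idx <- xyz_to_index(grid[, 1], grid[, 2], grid[, 3], dims)
  idx[as.vector(keep)]
}

#' Place stained somata with known ground truth
#'
#' Draws the number of cells Poisson around `density_mean x tissue
#' volume`, then places sphere somata by rejection sampling so that no two
#' somata overlap (centre separation at least the sum of their radii) and
#' every soma lies entirely inside the tissue mask.
#'
#' @param spec a `phantom_spec`.
#' @param rng_seed integer seed; the same spec and seed always reproduce
#'   the same table.
#' @return a `ground_truth` data.frame with columns `id`, `center_x_um`,
#'   `center_y_um`, `center_z_um`, `equiv_diam_um` (the true sampled soma
#'   diameter), `n_voxels` (rasterised soma voxel count) and `condition`;
#'   attributes `expected_count`, `tissue_volume_mm3`, `voxel_size_um`.
#' @export
place_somata <- function(spec, rng_seed = spec$seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  vol_mm3 <- tissue_volume_mm3(spec)
  expected <- spec$density_mean * vol_mm3
  ext <- spec$shape * spec$voxel_size_um
  with_seed(rng_seed, {
    n <- if (expected == 0) 0L else rpois(1L, expected)
    diam <- if (n > 0) {
      runif(n, spec$soma_diameter_range[1], spec$soma_diameter_range[2])
    } else {
      numeric(0)
    }
    centers <- matrix(NA_real_, nrow = n, ncol = 3)
    radii <- diam / 2
    max_tries <- 1000L * max(n, 1L)
    tries <- 0L
    placed <- 0L
    while (placed < n) {
      tries <- tries + 1L
      if (tries > max_tries) {
        stop(sprintf(
          paste0(
            "could not place %d somata in %.3g mm^3 of tissue with ",
            "non-overlap separation (sum of radii) and an in-tissue ",
            "margin of one soma radius; tissue volume too small for the ",
            "requested density/size"
          ), n, vol_mm3
        ))
      }
      cand <- runif(3) * ext
      r <- radii[placed + 1L]
      if (!point_in_tissue(cand, spec, r)) next
      if (placed > 0L) {
        dd <- sqrt(colSums((t(centers[seq_len(placed), , drop = FALSE]) -
                              cand)^2))
        if (any(dd < radii[seq_len(placed)] + r)) next
      }
      placed <- placed + 1L
      centers[placed, ] <- cand
    }
    nvox <- integer(n)
    for (k in seq_len(n)) {
      nvox[k] <- length(sphere_voxel_indices(centers[k, ], radii[k],
                                             spec$shape,
                                             spec$voxel_size_um))
    }
    truth <- data.frame(
      id = seq_len(n),
      center_x_um = centers[, 1][seq_len(n)],
      center_y_um = centers[, 2][seq_len(n)],
      center_z_um = centers[, 3][seq_len(n)],
      equiv_diam_um = diam,
      n_voxels = nvox,
      condition = rep(spec$condition, n)
    )
    attr(truth, "expected_count") <- expected
    attr(truth, "tissue_volume_mm3") <- vol_mm3
    attr(truth, "voxel_size_um") <- spec$voxel_size_um
    class(truth) <- c("ground_truth", "data.frame")
    truth
  })
}

## rotate direction u by angle within max_turn of its current bearing
perturb_direction <- function(u, max_turn_rad) {
  ## random axis perpendicular to u
  repeat {
    v <- rnorm(3)
    v <- v - sum(v * u) * u
    nv <- sqrt(sum(v^2))
    if (nv > 1e-8) break
  }
  v <- v / nv
  ang <- runif(1, 0, max_turn_rad)
  u2 <- cos(ang) * u + sin(ang) * v
  u2 / sqrt(sum(u2^2))
}

#' Grow neurites as persistent random-walk tubes
#'
#' Each cell receives `k` neurites (`k` uniform over
#' `neurite_count_range`) grown as random walks that start at the soma
#' centre, exit through the soma surface and persist with a turning angle
#' of at most 30 degrees per voxel-length step. Tubes are rasterised with
#' their sampled radius but always at least one voxel thick, so neurites
#' thinner than the voxel size do not vanish. A walk terminates when it
#' reaches its sampled length or leaves the tissue mask, which keeps every
#' neurite voxel 26-connected to its soma.
#'
#' Because neurite radii sit near (often below) the voxel size, each
#' neurite voxel carries a partial-volume fill fraction
#' `min(1, pi * r^2 / voxel_size^2)` — the fraction of the voxel
#' cross-section the tube occupies. Rasterisation mixes stain and
#' surround attenuation by this fraction, so sub-resolution neurites
#' image dimmer than somata, as they do in real scans.
#'
#' @param truth a `ground_truth` table from [place_somata()].
#' @param spec the `phantom_spec` used to generate it.
#' @param rng_seed integer seed.
#' @return a `stained_voxels` object: per-cell lists `soma` and `neurite`
#'   of linear voxel indices, a parallel per-cell list `neurite_fill` of
#'   fill fractions, plus the grid dims.
#' @export
grow_neurites <- function(truth, spec, rng_seed = spec$seed + 1L) {
  stopifnot(inherits(truth, "ground_truth"), inherits(spec, "phantom_spec"))
  d <- spec$shape
  vs <- spec$voxel_size_um
  mask <- tissue_mask_array(spec)
  n <- nrow(truth)
  soma <- vector("list", n)
  neur <- vector("list", n)
  fill <- vector("list", n)
  max_turn <- 30 * pi / 180
  with_seed(rng_seed, {
    for (k in seq_len(n)) {
      ctr <- as.numeric(truth[k, c("center_x_um", "center_y_um",
                                   "center_z_um")])
      r_soma <- truth$equiv_diam_um[k] / 2
      soma[[k]] <- sphere_voxel_indices(ctr, r_soma, d, vs)
      kvals <- spec$neurite_count_range[1]:spec$neurite_count_range[2]
      kcount <- kvals[sample.int(length(kvals), 1L)]
      vox <- integer(0)
      vfill <- numeric(0)
      for (j in seq_len(kcount)) {
        radius <- runif(1, spec$neurite_radius_range[1],
                        spec$neurite_radius_range[2])
        len <- runif(1, spec$neurite_length_range[1],
                     spec$neurite_length_range[2])
        tube_fill <- min(1, pi * radius^2 / vs^2)
        u <- rnorm(3)
        u <- u / sqrt(sum(u^2))
        nsteps <- max(1L, ceiling((r_soma + len) / vs))
        p <- ctr
        for (s in seq_len(nsteps)) {
          p <- p + u * vs
          ## nearest voxel (anti-vanishing) plus the tube cross-section
          nearest <- pmin(pmax(as.integer(floor(p / vs)), 0L), d - 1L)
          stamp <- sphere_voxel_indices(p, max(radius, 0), d, vs)
          stamp <- unique(c(xyz_to_index(nearest[1], nearest[2],
                                         nearest[3], d), stamp))
          inmask <- mask[stamp]
          if (!mask[stamp[1]]) break  # walk left the tissue: terminate
          vox <- c(vox, stamp[inmask])
          vfill <- c(vfill, rep(tube_fill, sum(inmask)))
          u <- perturb_direction(u, max_turn)
        }
      }
      ## aggregate shared voxels at the max fill; drop soma-interior ones
      if (length(vox) > 0) {
        agg <- tapply(vfill, vox, max)
        vox <- as.integer(names(agg))
        vfill <- as.numeric(agg)
        keep <- !(vox %in% soma[[k]])
        vox <- vox[keep]
        vfill <- vfill[keep]
      }
      neur[[k]] <- vox
      fill[[k]] <- vfill
    }
  })
  structure(list(soma = soma, neurite = neur, neurite_fill = fill,
                 dims = d),
            class = "stained_voxels")
}

#' Rasterise a phantom into an attenuation volume
#'
#' Assigns the embedding-medium attenuation inside the inscribed scan
#' cylinder (the sample holder region seen by the rotating scan), the
#' tissue attenuation inside the tissue mask, and the stain attenuation at
#' every stained voxel; stain overrides tissue. Voxels stained by more
#' than one cell are counted and attributed to the lower cell id in the
#' generation log.
#'
#' @param spec a `phantom_spec`.
#' @param truth a `ground_truth` table.
#' @param stained optional `stained_voxels` from [grow_neurites()]; if
#'   `NULL`, only the somata are stained.
#' @return a `tomo_volume` of kind `"attenuation"` with attribute
#'   `generation_log` (stained voxel count, stained volume in mm^3,
#'   overlap count).
#' @export
rasterize_phantom <- function(spec, truth, stained = NULL) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(truth, "ground_truth"))
  d <- spec$shape
  vs <- spec$voxel_size_um
  arr <- array(0, dim = d)
  ## scan cylinder: the region the acquisition can reconstruct
  rx <- min(d[1], d[2]) / 2
  cx <- d[1] / 2
  cy <- d[2] / 2
  fx <- (seq_len(d[1]) - 0.5 - cx)^2
  fy <- (seq_len(d[2]) - 0.5 - cy)^2
  cyl <- outer(fx, fy, "+") <= rx^2
  for (z in seq_len(d[3])) {
    arr[, , z][cyl] <- spec$attenuation_background
  }
  mask <- tissue_mask_array(spec)
  arr[mask] <- spec$attenuation_tissue
  if (is.null(stained)) {
    stained <- list(
      soma = lapply(seq_len(nrow(truth)), function(k) {
        sphere_voxel_indices(
          as.numeric(truth[k, c("center_x_um", "center_y_um",
                                "center_z_um")]),
          truth$equiv_diam_um[k] / 2, d, vs
        )
      }),
      neurite = rep(list(integer(0)), nrow(truth)),
      neurite_fill = rep(list(numeric(0)), nrow(truth)),
      dims = d
    )
  }
  per_cell <- mapply(c, stained$soma, stained$neurite, SIMPLIFY = FALSE)
  all_idx <- unlist(per_cell, use.names = FALSE)
  uniq <- unique(all_idx)
  overlap <- length(all_idx) - length(uniq)
  ## stain mixes into the surrounding material by the fill fraction;
  ## somata are full voxels, sub-resolution neurites partial.  Cells are
  ## applied in decreasing id order so overlaps resolve to the lower id.
  for (k in rev(seq_len(nrow(truth)))) {
    svox <- stained$soma[[k]]
    arr[svox] <- spec$attenuation_stain
    nvox <- stained$neurite[[k]]
    if (length(nvox) > 0) {
      f <- stained$neurite_fill[[k]]
      if (is.null(f)) f <- rep(1, length(nvox))
      arr[nvox] <- arr[nvox] + f * (spec$attenuation_stain - arr[nvox])
    }
  }
  vol <- tomo_volume(arr, vs, "attenuation")
  attr(vol, "generation_log") <- list(
    stained_voxel_count = length(uniq),
    stained_volume_mm3 = length(uniq) * voxel_volume_mm3(vs),
    overlap_voxel_count = overlap,
    overlap_rule = "overlapping stained voxels attributed to lower cell id"
  )
  vol
}

#' Generate a full phantom (somata, neurites, attenuation volume)
#'
#' Convenience wrapper running [place_somata()], [grow_neurites()] and
#' [rasterize_phantom()] with seeds derived from one seed.
#'
#' @param spec a `phantom_spec`.
#' @param rng_seed integer seed.
#' @param neurites grow neurites? (`FALSE` gives soma-only phantoms).
#' @return list with elements `volume`, `truth`, `stained`.
#' @export
build_phantom <- function(spec, rng_seed = spec$seed, neurites = TRUE) {
  truth <- place_somata(spec, rng_seed = stage_seed(rng_seed, "somata"))
  stained <- if (neurites) {
    grow_neurites(truth, spec, rng_seed = stage_seed(rng_seed, "neurites"))
  } else {
    NULL
  }
  volume <- rasterize_phantom(spec, truth, stained)
  list(volume = volume, truth = truth, stained = stained)
}

#' Generate replicate phantoms for two experimental conditions
#'
#' Per replicate, the target density is drawn from a normal distribution
#' `N(density_mean, density_sd_between)` truncated at zero, emulating
#' animal-to-animal variability, and somata are placed at that density.
#' Defaults follow the hippocampal control vs SE group summaries of
#' [golgi_density_presets()].
#'
#' @param spec_control,spec_se `phantom_spec`s for the two arms.
#' @param n_replicates replicates per arm (at least 2; 5 matches the
#'   published group size).
#' @param rng_seed integer seed.
#' @param rasterize build full volumes (`TRUE`) or ground truth only.
#' @return list with elements `control` and `se`, each a list of
#'   replicates `list(volume, truth, density_target)`.
#' @export
generate_condition_pair <- function(spec_control =
                                      phantom_spec(density_mean = 38.51,
                                                   density_sd_between = 5.5),
                                    spec_se =
                                      phantom_spec(density_mean = 19.32,
                                                   density_sd_between = 1.6,
                                                   condition = "SE"),
                                    n_replicates = 5L,
                                    rng_seed = 1L,
                                    rasterize = TRUE) {
  if (n_replicates < 2L) stop("`n_replicates` must be at least 2")
  arms <- list(control = spec_control, se = spec_se)
  out <- list()
  for (arm in names(arms)) {
    spec <- arms[[arm]]
    reps <- vector("list", n_replicates)
    for (r in seq_len(n_replicates)) {
      seed_r <- stage_seed(rng_seed, paste0(arm, "-replicate-", r))
      dens <- with_seed(seed_r, {
        repeat {
          dtry <- rnorm(1, spec$density_mean, spec$density_sd_between)
          if (dtry >= 0) break
        }
        dtry
      })
      spec_r <- spec
      spec_r$density_mean <- dens
      spec_r$density_sd_between <- 0
      if (rasterize) {
        ph <- build_phantom(spec_r, rng_seed = seed_r + 1L)
        reps[[r]] <- list(volume = ph$volume, truth = ph$truth,
                          density_target = dens)
      } else {
        truth <- place_somata(spec_r, rng_seed = seed_r + 1L)
        reps[[r]] <- list(volume = NULL, truth = truth,
                          density_target = dens)
      }
    }
    out[[arm]] <- reps
  }
  out
}

#' Realised stained-cell density of a ground-truth table
#'
#' @param truth a `ground_truth` table.
#' @return realised density, cells/mm^3 of tissue.
#' @export
realized_density <- function(truth) {
  nrow(truth) / attr(truth, "tissue_volume_mm3")
}

#' Write / read a ground-truth table as tab-separated text
#'
#' @param truth a `ground_truth` table.
#' @param path file path.
#' @return `path` (write) or the table (read), invisibly for write.
#' @export
write_ground_truth <- function(truth, path) {
  write.table(as.data.frame(truth), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  truth <- read.delim(path, sep = "\t")
  class(truth) <- c("ground_truth", "data.frame")
  truth
}
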