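#' Pipeline configuration
#'
#' Bundles the stage configurations of the end-to-end synthetic
#' experiment: phantom spec, acquisition geometry, reconstruction,
#' denoising, segmentation and quantification options, plus one global
#' seed from which every stage derives its own deterministic seed via
#' [stage_seed()].
#'
#' @param phantom a `phantom_spec`.
#' @param geometry an `acquisition_geometry`; by default sized to the
#'   phantom grid (centred axis, 180 degrees).
#' @param recon list: `filter_name`, `low_percentile`, `high_percentile`
#'   (8-bit window).
#' @param denoise list: `patch_radius`, `search_radius`, `h`.
#' @param segmentation a `segmentation_params`.
#' @param quantify list: `volume_basis`, `match_radius_um`,
#'   `min_equiv_diameter`.
#' @param noise simulate photon noise.
#' @param seed global seed.
#' @param out_dir optional output directory for stage artifacts.
#' @return a `run_config`.
#' @export
run_config <- function(phantom = phantom_spec(),
                       geometry = NULL,
                       recon = list(filter_name = "ramlak",
                                    low_percentile = 0.5,
                                    high_percentile = 99.999),
                       denoise = list(patch_radius = 2L,
                                      search_radius = 5L,
                                      h = "auto"),
                       segmentation = segmentation_params(),
                       quantify = list(volume_basis = "mask",
                                       match_radius_um = 10,
                                       min_equiv_diameter = 9),
                       noise = TRUE,
                       seed = 1L,
                       out_dir = NULL) {
  if (is.null(geometry)) {
    geometry <- acquisition_geometry(
      detector_width = phantom$shape[1],
      pixel_size_um = phantom$voxel_size_um,
      n_projections = max(2L, as.integer(ceiling(2 * phantom$shape[1] / 3))),
      angular_range = 180,
      axis_offset = 0L
    )
  }
  structure(
    list(phantom = phantom, geometry = geometry, recon = recon,
         denoise = denoise, segmentation = segmentation,
         quantify = quantify, noise = noise, seed = as.integer(seed),
         out_dir = out_dir),
    class = "run_config"
  )
}

#' Preset pipeline configurations
#'
#' * `"smoke"` — 256 x 256 x 128 voxels at 4.5 um, a fast end-to-end
#'   exercise of every stage (minutes on one CPU).
#' * `"validation"` — 512 x 512 x 256 voxels at 4.9 um, the standard
#'   phantom for quantitative count-recovery validation: large enough
#'   (about 3.5 mm^3 of tissue, 130+ expected cells at hippocampal
#'   control density) that Poisson counting fluctuation stays well
#'   inside a +/-15 percent density-error budget.
#' * `"cortex-hires"` — the published high-resolution cortex setup:
#'   0.82 um pixels, 2048-px detector, 2048 projections over 360 degrees,
#'   offset axis extending the detector to 3072 px. Full scale is a
#'   cluster-sized computation; scale `shape` down to run locally.
#' * `"hippocampus-lowres"` — the published low-resolution setup: 4.11 um
#'   pixels, otherwise as above, with hippocampal densities.
#'
#' Phantom presets use gray-seed ranges derived from the phantom's
#' three-material contrast (see the methods vignette) rather than the
#' tissue-scan defaults of [segmentation_params()].
#'
#' @param name preset name.
#' @param seed global seed.
#' @param density_mean,density_sd_between optional density overrides
#'   (cells/mm^3).
#' @return a `run_config`.
#' @export
preset_config <- function(name = c("smoke", "validation", "cortex-hires",
                                   "hippocampus-lowres"),
                          seed = 1L,
                          density_mean = NULL,
                          density_sd_between = NULL) {
  name <- match.arg(name)
  phantom_seg <- segmentation_params(
    brain_seed_range = c(34, 255),
    background_seed_range = c(0, 12)
  )
  if (name == "smoke") {
    ph <- phantom_spec(shape = c(256L, 256L, 128L), voxel_size_um = 4.5,
                       density_mean = density_mean %||% 31.08,
                       density_sd_between = density_sd_between %||% 0.5678)
    run_config(phantom = ph, segmentation = phantom_seg, seed = seed)
  } else if (name == "validation") {
    ph <- phantom_spec(shape = c(512L, 512L, 256L), voxel_size_um = 4.9,
                       density_mean = density_mean %||% 38.51,
                       density_sd_between = density_sd_between %||% 5.5)
    run_config(phantom = ph, segmentation = phantom_seg, seed = seed)
  } else if (name == "cortex-hires") {
    ph <- phantom_spec(shape = c(3072L, 3072L, 2048L), voxel_size_um = 0.82,
                       density_mean = density_mean %||% 31.08,
                       density_sd_between = density_sd_between %||% 0.5678)
    geom <- acquisition_geometry(detector_width = 2048L,
                                 pixel_size_um = 0.82,
                                 n_projections = 2048L,
                                 angular_range = 360,
                                 axis_offset = 512L)
    run_config(phantom = ph, geometry = geom, segmentation = phantom_seg,
               seed = seed)
  } else {
    ph <- phantom_spec(shape = c(3072L, 3072L, 2048L), voxel_size_um = 4.11,
                       density_mean = density_mean %||% 38.51,
                       density_sd_between = density_sd_between %||% 5.5)
    geom <- acquisition_geometry(detector_width = 2048L,
                                 pixel_size_um = 4.11,
                                 n_projections = 2048L,
                                 angular_range = 360,
                                 axis_offset = 512L)
    run_config(phantom = ph, geometry = geom, segmentation = phantom_seg,
               seed = seed)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the end-to-end pipeline
#'
#' Executes phantom generation, forward projection, photon-count
#' simulation, flat-field correction, extended-FOV composition (when the
#' axis is offset), filtered back-projection, 8-bit conversion, non-local
#' means denoising, brain masking, cell-body segmentation, the diameter
#' filter, density computation and ground-truth validation. Every stage
#' seeds its RNG from the global seed, so a config and seed reproduce the
#' run bit for bit.
#'
#' @param config a `run_config`.
#' @param keep_volumes keep intermediate volumes in the returned report
#'   (memory-heavy; default drops them).
#' @return a `pipeline_report` list: `cells`, `truth`, `density`,
#'   `metrics`, `comparison_to_spec`, `timings`, `warnings`, `config`.
#' @export
run_pipeline <- function(config, keep_volumes = FALSE) {
  stopifnot(inherits(config, "run_config"))
  t_all <- Sys.time()
  timings <- c()
  notes <- character(0)
  tick <- function(stage, start) {
    as.numeric(difftime(Sys.time(), start, units = "secs"))
  }

  t0 <- Sys.time()
  ph <- build_phantom(config$phantom, rng_seed = config$seed)
  timings["phantom"] <- tick("phantom", t0)
  glog <- attr(ph$volume, "generation_log")
  if (glog$overlap_voxel_count > 0) {
    notes <- c(notes, sprintf("%d overlapping stained voxels merged",
                              glog$overlap_voxel_count))
  }

  t0 <- Sys.time()
  sino <- forward_project(ph$volume, config$geometry)
  timings["project"] <- tick("project", t0)
  if (!keep_volumes) {
    ph$volume <- NULL
    gc(FALSE)
  }

  t0 <- Sys.time()
  counts <- simulate_counts(sino, noise = config$noise,
                            rng_seed = stage_seed(config$seed, "counts"))
  absorb <- flat_field_correct(counts$projections, counts$flat,
                               counts$dark, geometry = sino$geometry)
  nclip <- attr(absorb$data, "clip_count") %||% 0L
  if (is.null(nclip)) nclip <- 0L
  rm(counts, sino)
  gc(FALSE)
  timings["counts_flatfield"] <- tick("counts", t0)

  t0 <- Sys.time()
  if (config$geometry$axis_offset > 0) {
    absorb <- compose_extended_sinogram(absorb)
    notes <- c(notes, sprintf("extended-FOV composition to %d px",
                              absorb$composed_width))
  }
  recon <- fbp_reconstruct(absorb, config$recon$filter_name)
  rm(absorb)
  gc(FALSE)
  timings["reconstruct"] <- tick("recon", t0)

  t0 <- Sys.time()
  gray <- to_8bit(recon, config$recon$low_percentile,
                  config$recon$high_percentile)
  rm(recon)
  gc(FALSE)
  den <- nlm_denoise(gray, config$denoise$patch_radius,
                     config$denoise$search_radius, config$denoise$h)
  if (!keep_volumes) rm(gray)
  gc(FALSE)
  timings["to8bit_denoise"] <- tick("denoise", t0)

  t0 <- Sys.time()
  mask <- brain_mask(den, config$segmentation)
  gc(FALSE)
  seg <- segment_cell_bodies(den, config$segmentation)
  cells <- filter_by_diameter(seg$cells,
                              config$quantify$min_equiv_diameter)
  timings["segment"] <- tick("segment", t0)

  t0 <- Sys.time()
  density <- cell_density(cells, mask,
                          volume_basis = config$quantify$volume_basis)
  metrics <- match_to_ground_truth(cells, ph$truth,
                                   config$quantify$match_radius_um)
  timings["quantify"] <- tick("quantify", t0)
  timings["total"] <- as.numeric(difftime(Sys.time(), t_all,
                                          units = "secs"))

  spec_density <- config$phantom$density_mean
  report <- structure(
    list(
      n_cells_raw = nrow(seg$cells),
      n_cells = nrow(cells),
      cells = cells,
      truth = ph$truth,
      density = density,
      metrics = metrics,
      comparison_to_spec = list(
        spec_density = spec_density,
        measured_density = density$density_cells_per_mm3,
        relative_error = density$density_cells_per_mm3 / spec_density - 1,
        realized_truth_density = realized_density(ph$truth)
      ),
      generation_log = glog,
      clip_count = nclip,
      timings = timings,
      warnings = notes,
      config = config,
      volumes = if (keep_volumes) list(phantom = ph$volume,
                                       gray = gray,
                                       denoised = den,
                                       mask = mask) else NULL
    ),
    class = "pipeline_report"
  )
  if (!is.null(config$out_dir)) {
    persist_report(report, den, mask, seg$labels, config$out_dir)
  }
  report
}

persist_report <- function(report, denoised, mask, labels, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_ground_truth(report$truth, file.path(out_dir, "ground_truth.tsv"))
  write_cell_table(report$cells, file.path(out_dir, "cells.tsv"))
  cfg <- report$config
  cfg_list <- list(
    phantom = unclass(cfg$phantom),
    geometry = unclass(cfg$geometry),
    recon = cfg$recon,
    denoise = cfg$denoise,
    segmentation = unclass(cfg$segmentation),
    quantify = cfg$quantify,
    noise = cfg$noise,
    seed = cfg$seed
  )
  yaml::write_yaml(cfg_list, file.path(out_dir, "config.yaml"))
  summary <- list(
    n_cells = report$n_cells,
    density_cells_per_mm3 = report$density$density_cells_per_mm3,
    reference_volume_mm3 = report$density$reference_volume_mm3,
    f1 = report$metrics$f1,
    precision = report$metrics$precision,
    recall = report$metrics$recall,
    warnings = as.list(report$warnings),
    timings_sec = as.list(report$timings)
  )
  yaml::write_yaml(summary, file.path(out_dir, "report.yaml"))
  write_volume(denoised, file.path(out_dir, "denoised.tif"))
  write_volume(mask, file.path(out_dir, "brain_mask.tif"))
  write_volume(labels, file.path(out_dir, "cell_labels.tif"))
  invisible(out_dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  cells: %d segmented (%d before size filter)\n",
              x$n_cells, x$n_cells_raw))
  print(x$density)
  cat(sprintf("  detection vs truth: precision %.3f, recall %.3f, F1 %.3f\n",
              x$metrics$precision, x$metrics$recall, x$metrics$f1))
  cat(sprintf("  spec density %.4g, measured %.4g (%.1f%% error)\n",
              x$comparison_to_spec$spec_density,
              x$comparison_to_spec$measured_density,
              100 * x$comparison_to_spec$relative_error))
  cat(sprintf("  total runtime: %.1f s\n", x$timings["total"]))
  invisible(x)
}

#' Placement-level two-condition experiment
#'
#' Generates `n_replicates` phantom ground-truth tables per condition via
#' [generate_condition_pair()] (no imaging; the placement process itself
#' realises the between-replicate and Poisson variability), computes the
#' realised stained-cell densities, and compares the two arms with the
#' pooled Student's t test.
#'
#' @param spec_control,spec_se `phantom_spec`s for the two arms.
#' @param n_replicates replicates per arm.
#' @param rng_seed integer seed.
#' @param alpha significance level.
#' @return list with `densities_control`, `densities_se`, `comparison`.
#' @export
run_condition_experiment <- function(spec_control, spec_se,
                                     n_replicates = 5L, rng_seed = 1L,
                                     alpha = 0.05) {
  pair <- generate_condition_pair(spec_control, spec_se,
                                  n_replicates = n_replicates,
                                  rng_seed = rng_seed, rasterize = FALSE)
  dens_c <- vapply(pair$control, function(r) realized_density(r$truth),
                   numeric(1))
  dens_s <- vapply(pair$se, function(r) realized_density(r$truth),
                   numeric(1))
  list(
    densities_control = dens_c,
    densities_se = dens_s,
    comparison = compare_groups(dens_c, dens_s, alpha = alpha)
  )
}
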