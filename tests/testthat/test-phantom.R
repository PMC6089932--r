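test_that("phantom spec validates its invariants", {
  expect_s3_class(phantom_spec(), "phantom_spec")
  expect_error(phantom_spec(voxel_size_um = 6), "resolvable")
  expect_error(phantom_spec(attenuation_stain = 0.1), "stain > tissue")
  expect_error(phantom_spec(labeling_fraction = 1.5), "labeling_fraction")
  expect_error(phantom_spec(shape = c(0, 10, 10)), "positive")
})

test_that("soma placement realises the requested density", {
  ## 8 mm^3 of tissue at the printed cortex control density
  spec <- phantom_spec(shape = c(200L, 200L, 200L), voxel_size_um = 10,
                       tissue_mask = "full", density_mean = 31.08,
                       soma_diameter_range = c(21, 25),
                       neurite_count_range = c(0L, 0L))
  expect_equal(tissue_volume_mm3(spec), 8)
  truth <- place_somata(spec, rng_seed = 11)
  expected <- attr(truth, "expected_count")
  expect_equal(expected, 31.08 * 8)
  ## realised count within the central 99% Poisson interval
  interval <- qpois(c(0.005, 0.995), expected)
  expect_gte(nrow(truth), interval[1])
  expect_lte(nrow(truth), interval[2])
  ## table invariants
  expect_identical(truth$id, seq_len(nrow(truth)))
  expect_true(all(truth$n_voxels > 0))
  expect_true(all(truth$equiv_diam_um >= 21 & truth$equiv_diam_um <= 25))
})

test_that("zero expected count gives an empty table", {
  spec <- phantom_spec(shape = c(40L, 40L, 40L), voxel_size_um = 10,
                       density_mean = 0,
                       soma_diameter_range = c(21, 25))
  truth <- place_somata(spec, rng_seed = 1)
  expect_identical(nrow(truth), 0L)
})

test_that("placement is deterministic given the seed", {
  spec <- small_spec()
  t1 <- place_somata(spec, rng_seed = 5)
  t2 <- place_somata(spec, rng_seed = 5)
  expect_identical(t1, t2)
  t3 <- place_somata(spec, rng_seed = 6)
  expect_false(identical(t1, t3))
})

test_that("somata never overlap and stay inside the tissue", {
  spec <- small_spec()
  truth <- place_somata(spec, rng_seed = 3)
  expect_gt(nrow(truth), 2)
  ctr <- as.matrix(truth[, c("center_x_um", "center_y_um", "center_z_um")])
  r <- truth$equiv_diam_um / 2
  for (i in seq_len(nrow(truth) - 1)) {
    for (j in (i + 1):nrow(truth)) {
      d <- sqrt(sum((ctr[i, ] - ctr[j, ])^2))
      expect_gte(d, r[i] + r[j])
    }
  }
  mask <- tissue_mask_array(spec)
  vs <- spec$voxel_size_um
  vox <- floor(ctr / vs)
  expect_true(all(mask[vox + 1]))
})

test_that("an impossible packing fails with an informative error", {
  spec <- phantom_spec(shape = c(24L, 24L, 24L), voxel_size_um = 10,
                       tissue_mask = "full", density_mean = 40000,
                       soma_diameter_range = c(50, 60),
                       neurite_count_range = c(0L, 0L))
  expect_error(place_somata(spec, rng_seed = 1), "tissue volume too small")
})

test_that("count recovery sharpens as the tissue volume grows", {
  mk <- function(n) {
    phantom_spec(shape = c(n, n, n), voxel_size_um = 10,
                 tissue_mask = "full", density_mean = 31.08,
                 soma_diameter_range = c(21, 25),
                 neurite_count_range = c(0L, 0L))
  }
  rel_err <- function(spec, seeds) {
    vapply(seeds, function(s) {
      tr <- place_somata(spec, rng_seed = s)
      abs(nrow(tr) / attr(tr, "expected_count") - 1)
    }, numeric(1))
  }
  seeds <- 1:10
  e_small <- rel_err(mk(200L), seeds)   # 8 mm^3
  e_large <- rel_err(mk(400L), seeds)   # 64 mm^3
  expect_lt(mean(e_large), mean(e_small))
})

test_that("neurite growth respects count range, thickness and connectivity", {
  spec0 <- small_spec()
  truth <- place_somata(spec0, rng_seed = 2)
  ## zero neurites: stained voxels are exactly the soma voxels
  st0 <- grow_neurites(truth, spec0, rng_seed = 4)
  expect_true(all(lengths(st0$neurite) == 0))
  expect_identical(sum(lengths(st0$soma)), sum(truth$n_voxels))

  ## sub-voxel radius still rasterises a contiguous >= 1 voxel tube
  spec1 <- phantom_spec(shape = c(96L, 96L, 48L), voxel_size_um = 4.5,
                        density_mean = 100, density_sd_between = 0,
                        soma_diameter_range = c(15, 22),
                        neurite_count_range = c(2L, 3L),
                        neurite_radius_range = c(2.25, 2.25),
                        neurite_length_range = c(30, 60))
  truth1 <- place_somata(spec1, rng_seed = 2)
  st1 <- grow_neurites(truth1, spec1, rng_seed = 9)
  expect_gt(sum(lengths(st1$neurite)), 0)
  ## partial-volume fill recorded and positive
  fills <- unlist(st1$neurite_fill)
  expect_true(all(fills > 0 & fills <= 1))
  ## every neurite voxel reachable from its soma (flood-fill oracle)
  for (k in seq_len(nrow(truth1))) {
    if (length(st1$neurite[[k]]) == 0) next
    cellset <- c(st1$soma[[k]], st1$neurite[[k]])
    reached <- flood_reachable(st1$soma[[k]], cellset, spec1$shape)
    expect_setequal(reached, cellset)
  }
})

test_that("rasterisation assigns the three materials coherently", {
  spec <- small_spec()
  ## empty truth: only background and tissue
  empty <- place_somata(phantom_spec(shape = spec$shape,
                                     voxel_size_um = spec$voxel_size_um,
                                     density_mean = 0,
                                     soma_diameter_range = c(15, 22)),
                        rng_seed = 1)
  vol0 <- rasterize_phantom(spec, empty)
  expect_setequal(unique(as.vector(vol0$data)),
                  c(0, spec$attenuation_background, spec$attenuation_tissue))

  truth <- place_somata(spec, rng_seed = 3)
  st <- grow_neurites(truth, spec, rng_seed = 4)
  vol <- rasterize_phantom(spec, truth, st)
  log <- attr(vol, "generation_log")
  ## bookkeeping identity: stained volume = stained voxels x voxel volume
  expect_equal(log$stained_volume_mm3,
               log$stained_voxel_count * voxel_volume_mm3(spec$voxel_size_um))
  ## soma voxels carry the stain attenuation exactly
  expect_true(all(vol$data[unlist(st$soma)] == spec$attenuation_stain))
  ## noise-free soma-only phantom: exactly 3 attenuation levels
  vol_s <- rasterize_phantom(spec, truth, NULL)
  expect_identical(length(unique(as.vector(vol_s$data))), 4L)  # + outside 0
  expect_setequal(unique(as.vector(vol_s$data)),
                  c(0, spec$attenuation_background, spec$attenuation_tissue,
                    spec$attenuation_stain))
})

test_that("same spec and seed give bit-identical phantoms", {
  spec <- small_spec()
  a <- build_phantom(spec, rng_seed = 21)
  b <- build_phantom(spec, rng_seed = 21)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$truth, b$truth)
})

test_that("condition pairs draw replicate densities around the group means", {
  shp <- c(128L, 128L, 64L)
  sc <- phantom_spec(shape = shp, voxel_size_um = 4.9,
                     density_mean = 38.51, density_sd_between = 5.5,
                     neurite_count_range = c(0L, 0L))
  ss <- phantom_spec(shape = shp, voxel_size_um = 4.9,
                     density_mean = 19.32, density_sd_between = 1.6,
                     neurite_count_range = c(0L, 0L), condition = "SE")
  pair <- generate_condition_pair(sc, ss, n_replicates = 5L, rng_seed = 2,
                                  rasterize = FALSE)
  expect_length(pair$control, 5L)
  expect_length(pair$se, 5L)
  targets_c <- vapply(pair$control, `[[`, numeric(1), "density_target")
  targets_s <- vapply(pair$se, `[[`, numeric(1), "density_target")
  expect_true(all(targets_c >= 0) && all(targets_s >= 0))
  expect_gt(mean(targets_c), mean(targets_s))
  ## zero between-replicate spread: identical expectations
  sc0 <- sc
  sc0$density_sd_between <- 0
  pair0 <- generate_condition_pair(sc0, ss, n_replicates = 3L, rng_seed = 2,
                                   rasterize = FALSE)
  exp0 <- vapply(pair0$control, function(r) attr(r$truth, "expected_count"),
                 numeric(1))
  expect_identical(length(unique(exp0)), 1L)
  expect_error(generate_condition_pair(sc, ss, n_replicates = 1L),
               "at least 2")
})

test_that("replicate control densities bracket the printed group mean", {
  ## mean realised control density across replicates stays within one
  ## printed SD of the printed hippocampal control mean
  shp <- c(256L, 256L, 128L)
  sc <- phantom_spec(shape = shp, voxel_size_um = 4.9,
                     density_mean = 38.51, density_sd_between = 5.5,
                     neurite_count_range = c(0L, 0L))
  ss <- phantom_spec(shape = shp, voxel_size_um = 4.9,
                     density_mean = 19.32, density_sd_between = 1.6,
                     neurite_count_range = c(0L, 0L), condition = "SE")
  means <- vapply(1:20, function(s) {
    pair <- generate_condition_pair(sc, ss, n_replicates = 5L,
                                    rng_seed = 100 + s, rasterize = FALSE)
    mean(vapply(pair$control, function(r) realized_density(r$truth),
                numeric(1)))
  }, numeric(1))
  expect_gt(mean(means), 33.0)
  expect_lt(mean(means), 44.0)
})

test_that("ground truth round-trips through TSV", {
  truth <- place_somata(small_spec(), rng_seed = 8)
  path <- tempfile(fileext = ".tsv")
  write_ground_truth(truth, path)
  back <- read_ground_truth(path)
  expect_equal(as.data.frame(back), as.data.frame(truth),
               tolerance = 1e-10, ignore_attr = TRUE)
  unlink(path)
})
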