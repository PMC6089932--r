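make_sphere_volume <- function(centers_um, diam_um, n = 64, nz = 32,
                               vs = 1, fg = 200, bg = 30) {
  arr <- array(bg, dim = c(n, n, nz))
  for (k in seq_len(nrow(centers_um))) {
    idx <- neurotomo:::sphere_voxel_indices(centers_um[k, ], diam_um[k] / 2,
                                            c(n, n, nz), vs)
    arr[idx] <- fg
  }
  tomo_volume(arr, vs, "gray8")
}

test_that("segmentation parameter defaults follow the published recipe", {
  p <- segmentation_params()
  expect_equal(p$brain_seed_range, c(130, 255))
  expect_equal(p$background_seed_range, c(0, 126))
  expect_equal(p$cellbody_threshold_range, c(142, 255))
  expect_equal(p$neuron_threshold_range, c(139, 255))
  expect_equal(p$min_equiv_diameter, 9)
  expect_error(segmentation_params(brain_seed_range = c(100, 255)),
               "disjoint")
  expect_error(segmentation_params(cellbody_threshold_range = c(0, 300)),
               "within")
})

test_that("component labelling matches connectivity semantics", {
  ## two voxels sharing only a corner
  m <- array(FALSE, dim = c(4, 4, 4))
  m[1, 1, 1] <- TRUE
  m[2, 2, 2] <- TRUE
  expect_identical(attr(label_components(m, 26L), "n_components"), 1L)
  expect_identical(attr(label_components(m, 6L), "n_components"), 2L)
  ## empty mask
  expect_identical(
    attr(label_components(array(FALSE, dim = c(3, 3, 3))), "n_components"),
    0L
  )
})

test_that("component labelling agrees with an independent oracle", {
  set.seed(99)
  for (k in 1:50) {
    m <- array(runif(32^3) < runif(1, 0.05, 0.5), dim = c(32, 32, 32))
    conn <- sample(c(6L, 26L), 1)
    lab <- label_components(m, conn)
    orc <- oracle_components(m, conn)
    expect_identical(attr(lab, "n_components"),
                     length(unique(orc[orc > 0])))
    expect_true(same_partition(lab$data, orc))
  }
})

test_that("labelling is deterministic in raster order", {
  set.seed(7)
  m <- array(runif(20^3) < 0.3, dim = c(20, 20, 20))
  lab <- label_components(m, 26L)$data
  firsts <- vapply(seq_len(max(lab)), function(l) min(which(lab == l)),
                   numeric(1))
  expect_true(all(diff(firsts) > 0))
})

test_that("cell bodies are measured on pre-dilation voxels", {
  centers <- rbind(c(16, 16, 16), c(44, 16, 16), c(30, 46, 16))
  vol <- make_sphere_volume(centers, rep(12, 3))
  seg <- segment_cell_bodies(vol)
  expect_identical(nrow(seg$cells), 3L)
  ## digitisation tolerance +/- 10% around the nominal 12 um
  expect_true(all(seg$cells$equiv_diameter_um > 10.8 &
                    seg$cells$equiv_diameter_um < 13.2))
  ## centroids at the sphere centres
  got <- as.matrix(seg$cells[, c("centroid_x_um", "centroid_y_um",
                                 "centroid_z_um")])
  ord <- order(got[, 1])
  expect_lt(max(abs(got[ord, ] - centers[order(centers[, 1]), ])), 0.8)
})

test_that("dilation merges close spheres into one component", {
  ## gap of 1 voxel < 2 x dilation radius: the pair merges
  centers <- rbind(c(20, 20, 16), c(33, 20, 16))
  vol <- make_sphere_volume(centers, rep(12, 2))
  seg <- segment_cell_bodies(vol)
  expect_identical(nrow(seg$cells), 1L)
})

test_that("an all-background volume yields an empty cell table", {
  vol <- tomo_volume(array(30, dim = c(16, 16, 16)), 1, "gray8")
  seg <- segment_cell_bodies(vol)
  expect_identical(nrow(seg$cells), 0L)
})

test_that("the diameter filter keeps strictly larger objects only", {
  tab <- data.frame(label = 1:3,
                    centroid_x_um = 0, centroid_y_um = 0, centroid_z_um = 0,
                    n_voxels = c(65L, 452L, 905L),
                    equiv_diameter_um = c(5, 9.5, 12))
  class(tab) <- c("cell_table", "data.frame")
  expect_identical(nrow(filter_by_diameter(tab, 9)), 2L)
  expect_identical(nrow(filter_by_diameter(tab, 0)), 3L)
  expect_identical(filter_by_diameter(tab, 9)$equiv_diameter_um, c(9.5, 12))
})

test_that("watershed brain mask recovers a noisy ellipsoid", {
  set.seed(21)
  n <- 64
  nz <- 48
  xs <- seq_len(n) - n / 2
  zs <- seq_len(nz) - nz / 2
  inside <- array(FALSE, dim = c(n, n, nz))
  for (z in seq_len(nz)) {
    inside[, , z] <- outer((xs / 26)^2, (xs / 22)^2, "+") +
      (zs[z] / 18)^2 <= 1
  }
  arr <- ifelse(inside, 180, 20) + rnorm(n * n * nz, 0, 6)
  vol <- tomo_volume(neurotomo:::clamp(round(arr), 0, 255), 4, "gray8")
  mask <- brain_mask(vol)  # default seed ranges
  got <- mask$data == 1
  iou <- sum(got & inside) / sum(got | inside)
  expect_gte(iou, 0.95)
  ## all-background volume exercises the failure path
  dark <- tomo_volume(array(20, dim = c(8, 8, 8)), 4, "gray8")
  expect_error(brain_mask(dark), "no brain seeds")
})

test_that("neuron segmentation keeps soma-neurite tubes and drops islands", {
  n <- 64
  arr <- array(30, dim = c(n, n, 16))
  vs <- 1
  soma_idx <- neurotomo:::sphere_voxel_indices(c(16, 32, 8), 6, c(n, n, 16), vs)
  arr[soma_idx] <- 200
  ## straight tube (radius 1 voxel) from the soma surface
  for (x in 22:52) arr[x, 32, 8] <- 200
  ## 1-3 voxel islands
  arr[5, 5, 2] <- 200
  arr[60, 60, 14] <- 200
  arr[60, 59, 14] <- 200
  vol <- tomo_volume(arr, vs, "gray8")
  lab <- segment_neurons(vol, segmentation_params(min_island_voxels = 10L))
  expect_identical(attr(lab, "n_components"), 1L)
  ## the surviving component spans soma and full tube length
  comp_idx <- which(lab$data > 0)
  expect_true(all(soma_idx %in% comp_idx))
  expect_true(lab$data[52, 32, 8] > 0)
  ## seeded selection and the out-of-volume error path
  lab2 <- segment_neurons(vol, segmentation_params(min_island_voxels = 1L),
                          seed_points = rbind(c(16, 32, 8)))
  expect_identical(attr(lab2, "n_components"), 1L)
  expect_error(
    segment_neurons(vol, seed_points = rbind(c(500, 2, 2))),
    "outside the volume"
  )
})

test_that("raising the lower threshold never increases component counts", {
  spec <- small_spec()
  ph <- build_phantom(spec, rng_seed = 55, neurites = FALSE)
  gray <- to_8bit(ph$volume, 0.5, 99.999)
  counts <- vapply(seq(130, 160, by = 5), function(lo) {
    p <- segmentation_params(cellbody_threshold_range = c(lo, 255))
    nrow(segment_cell_bodies(gray, p)$cells)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("segmentation counts are invariant to affine rescaling", {
  spec <- small_spec()
  ph <- build_phantom(spec, rng_seed = 56, neurites = FALSE)
  g1 <- to_8bit(ph$volume, 0.5, 99.999)
  scaled <- ph$volume
  scaled$data <- scaled$data * 3.7
  g2 <- to_8bit(scaled, 0.5, 99.999)
  expect_identical(g1$data, g2$data)
  expect_identical(nrow(segment_cell_bodies(g1)$cells),
                   nrow(segment_cell_bodies(g2)$cells))
})

test_that("equivalent diameter converges for well-resolved spheres", {
  for (diam_vox in c(10, 14)) {
    n <- diam_vox + 8
    idx <- neurotomo:::sphere_voxel_indices(rep(n / 2, 3), diam_vox / 2,
                                            c(n, n, n), 1)
    m <- array(FALSE, dim = c(n, n, n))
    m[idx] <- TRUE
    nvox <- sum(m)
    equiv <- (6 * nvox / pi)^(1 / 3)
    expect_lt(abs(equiv / diam_vox - 1), 0.05)
  }
})
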