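test_that("flat-field correction implements clipped Beer-Lambert", {
  flat <- array(1000, dim = c(8, 2))
  dark <- array(0, dim = c(8, 2))
  proj <- array(1000, dim = c(8, 4, 2))
  expect_equal(as.vector(flat_field_correct(proj, flat, dark)),
               rep(0, length(proj)))
  proj2 <- array(1000 * exp(-1), dim = c(8, 4, 2))
  expect_equal(as.vector(flat_field_correct(proj2, flat, dark)),
               rep(1, length(proj2)), tolerance = 1e-12)
  ## zero counts hit the epsilon clip and warn
  proj3 <- array(0, dim = c(8, 4, 2))
  expect_warning(a3 <- flat_field_correct(proj3, flat, dark), "clipped")
  expect_equal(as.vector(a3), rep(-log(1e-6), length(proj3)))
  expect_error(flat_field_correct(proj, flat * 0, dark), "all zero")
})

test_that("extended-FOV composition reproduces the published width", {
  ## 2048-px detector, axis 512 px inside one edge -> 3072 composed px
  g <- acquisition_geometry(detector_width = 2048L, pixel_size_um = 4.11,
                            n_projections = 8L, angular_range = 360,
                            axis_offset = 512L)
  sino <- neurotomo:::new_sinogram(array(0, dim = c(2048, 8, 1)), g, "absorbance")
  ext <- compose_extended_sinogram(sino)
  expect_identical(ext$composed_width, 3072L)
  expect_identical(ext$overlap_width, 1024L)  # 2 * (W/2 - offset)
  expect_identical(ext$geometry$n_projections, 4L)
  expect_identical(ext$geometry$angular_range, 180)
  ## invariant: composed = 2 * (W - edge_distance)
  e <- 2048 / 2 - 512
  expect_identical(ext$composed_width, as.integer(2 * (2048 - e)))
})

test_that("centred-axis composition degenerates to the identity width", {
  vol <- blob_volume(64, 10, seed = 5)
  g <- acquisition_geometry(detector_width = 64L, pixel_size_um = 10,
                            n_projections = 16L, angular_range = 360,
                            axis_offset = 0L)
  sino <- forward_project(vol, g)
  expect_error(compose_extended_sinogram(sino, blend = "ramp"),
               "plain 180")
  ext <- compose_extended_sinogram(sino, blend = "hard")
  expect_identical(ext$composed_width, 64L)
  direct <- forward_project(vol, acquisition_geometry(
    detector_width = 64L, pixel_size_um = 10, n_projections = 8L,
    angular_range = 180, axis_offset = 0L
  ))
  expect_lt(max(abs(ext$data - direct$data)) / max(direct$data), 1e-9)
})

test_that("offset-axis composition matches a wide-detector oracle scan", {
  n <- 256
  vol <- blob_volume(n, 10, seed = 17)
  g360 <- acquisition_geometry(detector_width = 192L, pixel_size_um = 10,
                               n_projections = 256L, angular_range = 360,
                               axis_offset = 32L)
  ext <- compose_extended_sinogram(forward_project(vol, g360))
  g180 <- acquisition_geometry(detector_width = 256L, pixel_size_um = 10,
                               n_projections = 128L, angular_range = 180)
  oracle <- forward_project(vol, g180)
  mx <- max(oracle$data)
  W <- 192L
  C <- 256L
  seam <- (C - W + 1):W
  offseam <- abs(ext$data - oracle$data)[-seam, , 1]
  expect_lt(max(offseam) / mx, 0.01)
})

test_that("FBP recovers a uniform disk to within 5% RMSE", {
  n <- 512
  R <- 64
  vol <- disk_volume(n, R, 1.0, 10)
  g <- acquisition_geometry(detector_width = n, pixel_size_um = 10,
                            n_projections = 804L, angular_range = 180)
  sino <- forward_project(vol, g)
  rec <- fbp_reconstruct(sino)
  xs <- seq_len(n) - 0.5 - n / 2
  inside <- outer(xs^2, xs^2, "+") <= (R - 2)^2
  rmse <- sqrt(mean((rec$data[, , 1][inside] - 1.0)^2))
  expect_lte(rmse, 0.05)
})

test_that("FBP is linear and maps zero to zero", {
  vol <- blob_volume(96, 10, seed = 2)
  g <- acquisition_geometry(detector_width = 96L, pixel_size_um = 10,
                            n_projections = 48L, angular_range = 180)
  sino <- forward_project(vol, g)
  zero <- sino
  zero$data[] <- 0
  expect_true(all(fbp_reconstruct(zero)$data == 0))
  r1 <- fbp_reconstruct(sino)
  s3 <- sino
  s3$data <- sino$data * 3
  r3 <- fbp_reconstruct(s3)
  expect_lt(max(abs(r3$data - 3 * r1$data)) / max(abs(r3$data)), 1e-9)
  expect_error(fbp_reconstruct(neurotomo:::new_sinogram(
    array(0, dim = c(96, 1, 1)),
    acquisition_geometry(detector_width = 96L, pixel_size_um = 10,
                         n_projections = 1L, angular_range = 180),
    "absorbance"
  )), "at least 2 angles")
})

test_that("noise-free round trip recovers the stain attenuation", {
  ## somata several voxels across at a Crowther-satisfying angle count;
  ## the plateau (interior voxels, one voxel in from the surface) carries
  ## the amplitude check since surface voxels are band-limited by any
  ## reconstruction
  spec <- phantom_spec(shape = c(96L, 96L, 64L), voxel_size_um = 3,
                       density_mean = 3000, density_sd_between = 0,
                       soma_diameter_range = c(20, 25),
                       neurite_count_range = c(0L, 0L))
  ph <- build_phantom(spec, rng_seed = 31)
  g <- acquisition_geometry(detector_width = 96L, pixel_size_um = 3,
                            n_projections = 160L, angular_range = 180)
  rec <- fbp_reconstruct(forward_project(ph$volume, g))
  interior <- unlist(lapply(seq_len(nrow(ph$truth)), function(k) {
    neurotomo:::sphere_voxel_indices(
      as.numeric(ph$truth[k, c("center_x_um", "center_y_um",
                               "center_z_um")]),
      ph$truth$equiv_diam_um[k] / 2 - spec$voxel_size_um, spec$shape,
      spec$voxel_size_um
    )
  }))
  expect_lt(abs(mean(rec$data[interior]) / spec$attenuation_stain - 1), 0.1)
})

test_that("extended-FOV and wide-detector paths segment identically", {
  spec <- phantom_spec(shape = c(128L, 128L, 32L), voxel_size_um = 4.5,
                       density_mean = 800, density_sd_between = 0,
                       soma_diameter_range = c(15, 22),
                       neurite_count_range = c(0L, 0L))
  ph <- build_phantom(spec, rng_seed = 13, neurites = FALSE)
  g360 <- acquisition_geometry(detector_width = 96L, pixel_size_um = 4.5,
                               n_projections = 256L, angular_range = 360,
                               axis_offset = 16L)
  ext <- compose_extended_sinogram(forward_project(ph$volume, g360))
  g180 <- acquisition_geometry(detector_width = 128L, pixel_size_um = 4.5,
                               n_projections = 128L, angular_range = 180)
  wide <- forward_project(ph$volume, g180)
  params <- segmentation_params()
  seg_ext <- segment_cell_bodies(
    to_8bit(fbp_reconstruct(ext), 0.5, 99.999), params
  )
  seg_wide <- segment_cell_bodies(
    to_8bit(fbp_reconstruct(wide), 0.5, 99.999), params
  )
  expect_gt(nrow(seg_wide$cells), 0)
  expect_identical(nrow(seg_ext$cells), nrow(seg_wide$cells))
})

test_that("8-bit conversion maps the percentile window linearly", {
  set.seed(4)
  arr <- array(runif(40^3, 0, 2), dim = c(40, 40, 40))
  vol <- tomo_volume(arr, 5, "attenuation")
  g <- to_8bit(vol, 1, 99)
  q <- quantile(arr, c(0.01, 0.99), names = FALSE)
  expect_identical(g$kind, "gray8")
  expect_true(all(g$data[arr <= q[1]] == 0))
  expect_true(all(g$data[arr >= q[2]] == 255))
  ## half-up rounding at an exactly representable midpoint
  mid <- array(c(q[1], (q[1] + q[2]) / 2, q[2]), dim = c(3, 1, 1))
  gm <- to_8bit(tomo_volume(mid, 5, "attenuation"), 0, 100)
  expect_identical(as.vector(gm$data), c(0, 128, 255))
  ## constant volume: warning and all-zero output
  cv <- tomo_volume(array(1, dim = c(4, 4, 4)), 5, "attenuation")
  expect_warning(gz <- to_8bit(cv), "degenerate")
  expect_true(all(gz$data == 0))
})

test_that("three-material phantoms stay separable on the 8-bit scale", {
  ## noise-free three-plateau volume (stain > 0.5% of voxels): three
  ## distinct gray plateaus with the stain plateau above the cell-body
  ## threshold of 142
  arr <- array(0.05, dim = c(32, 32, 32))
  arr[, , 9:32] <- 0.5
  arr[10:15, 10:15, 10:15] <- 5.0
  g <- to_8bit(tomo_volume(arr, 5, "attenuation"), 0.5, 99.5)
  plateaus <- sort(unique(as.vector(g$data)))
  expect_identical(length(plateaus), 3L)
  expect_gt(plateaus[3], 142)
})
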