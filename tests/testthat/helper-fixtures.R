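## Shared fixtures and independent oracles for the test suite.

## Independent connected-component oracle: iterative minimum-label
## propagation. Every foreground voxel starts with its own linear index
## as label; labels repeatedly take the minimum over their 26- (or 6-)
## neighbourhood within the mask until a fixed point. Components are then
## identified by their minimum linear index. This shares no code with the
## package's BFS labeller.
oracle_components <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  lab <- array(0, dim = d)
  lab[mask] <- which(mask)
  shifts <- list()
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    m <- abs(dx) + abs(dy) + abs(dz)
    if (m == 0) next
    if (connectivity == 6L && m > 1) next
    if (connectivity == 18L && m > 2) next
    shifts[[length(shifts) + 1]] <- c(dx, dy, dz)
  }
  shift_arr <- function(a, s) {
    out <- array(Inf, dim = d)
    src <- list(
      x = seq_len(d[1]) - s[1], y = seq_len(d[2]) - s[2],
      z = seq_len(d[3]) - s[3]
    )
    okx <- src$x >= 1 & src$x <= d[1]
    oky <- src$y >= 1 & src$y <= d[2]
    okz <- src$z >= 1 & src$z <= d[3]
    out[okx, oky, okz] <- a[src$x[okx], src$y[oky], src$z[okz]]
    out
  }
  lab[!mask] <- Inf
  repeat {
    new <- lab
    for (s in shifts) {
      new <- pmin(new, shift_arr(lab, s))
    }
    new[!mask] <- Inf
    if (identical(new, lab)) break
    lab <- new
  }
  lab[!mask] <- 0
  lab[is.infinite(lab)] <- 0
  lab
}

## partition equality of two labellings over the same foreground
same_partition <- function(lab_a, lab_b) {
  fg <- lab_a > 0
  if (!identical(fg, lab_b > 0)) return(FALSE)
  pairs <- unique(cbind(lab_a[fg], lab_b[fg]))
  nrow(pairs) == length(unique(pairs[, 1])) &&
    nrow(pairs) == length(unique(pairs[, 2]))
}

## reachability oracle: which voxels of `set_idx` are 26-connected to the
## seed voxels, by breadth-first expansion within the set
flood_reachable <- function(seed_idx, set_idx, dims) {
  inset <- array(FALSE, dim = dims)
  inset[set_idx] <- TRUE
  reach <- array(FALSE, dim = dims)
  reach[intersect(seed_idx, set_idx)] <- TRUE
  reach[seed_idx] <- TRUE
  repeat {
    grown <- reach
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      sx <- seq_len(dims[1]) - dx
      sy <- seq_len(dims[2]) - dy
      sz <- seq_len(dims[3]) - dz
      okx <- sx >= 1 & sx <= dims[1]
      oky <- sy >= 1 & sy <= dims[2]
      okz <- sz >= 1 & sz <= dims[3]
      tmp <- array(FALSE, dim = dims)
      tmp[okx, oky, okz] <- reach[sx[okx], sy[oky], sz[okz]]
      grown <- grown | (tmp & inset)
    }
    if (identical(grown, reach)) break
    reach <- grown
  }
  which(reach & inset)
}

## uniform disk slice (value mu inside radius_px), n x n x nz
disk_volume <- function(n, radius_px, mu, voxel_um, nz = 1) {
  xs <- seq_len(n) - 0.5 - n / 2
  r2 <- outer(xs^2, xs^2, "+")
  sl <- ifelse(r2 <= radius_px^2, mu, 0)
  tomo_volume(array(rep(sl, nz), dim = c(n, n, nz)), voxel_um,
              "attenuation")
}

## random blob phantom confined to the inscribed circle (for projection
## and stitching tests)
blob_volume <- function(n, voxel_um, nz = 1, n_blobs = 25, seed = 1) {
  set.seed(seed)
  xs <- seq_len(n) - 0.5 - n / 2
  r2 <- outer(xs^2, xs^2, "+")
  sl <- matrix(0, n, n)
  lim <- 0.72 * n / 2
  for (k in seq_len(n_blobs)) {
    cx <- runif(1, -lim, lim)
    cy <- runif(1, -lim, lim)
    rr <- runif(1, n / 100, n / 16)
    d2 <- outer((xs - cx)^2, (xs - cy)^2, "+")
    sl[d2 <= rr^2] <- sl[d2 <= rr^2] + runif(1, 0.2, 1)
  }
  sl[r2 > (0.94 * n / 2)^2] <- 0
  tomo_volume(array(rep(sl, nz), dim = c(n, n, nz)), voxel_um,
              "attenuation")
}

## small soma-only phantom spec for fast 3D tests
small_spec <- function(...) {
  phantom_spec(shape = c(96L, 96L, 48L), voxel_size_um = 4.5,
               density_mean = 300, density_sd_between = 0,
               soma_diameter_range = c(15, 22),
               neurite_count_range = c(0L, 0L), ...)
}
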