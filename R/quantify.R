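#' Cell density from a cell table
#'
#' Density is the object count divided by a reference volume: either the
#' segmented tissue-mask volume (`volume_basis = "mask"`, the default, so
#' densities are per unit of brain-structure volume) or the full imaged
#' grid volume (`"full_fov"`).
#'
#' @param cells a `cell_table`.
#' @param mask binary tissue mask (`tomo_volume` or logical array);
#'   required and non-empty for the `"mask"` basis.
#' @param voxel_size_um voxel size (defaults to the table's/mask's).
#' @param volume_basis `"mask"` or `"full_fov"`.
#' @param grid_shape grid dimensions for `"full_fov"` when no mask is
#'   given.
#' @return a `density_result`: list with `n_cells`, `reference_volume_mm3`,
#'   `density_cells_per_mm3`, `volume_basis`.
#' @export
cell_density <- function(cells, mask = NULL, voxel_size_um = NULL,
                         volume_basis = c("mask", "full_fov"),
                         grid_shape = NULL) {
  volume_basis <- match.arg(volume_basis)
  stopifnot(inherits(cells, "cell_table"))
  if (is.null(voxel_size_um)) {
    voxel_size_um <- if (inherits(mask, "tomo_volume")) {
      mask$voxel_size_um
    } else {
      attr(cells, "voxel_size_um")
    }
  }
  if (is.null(voxel_size_um)) stop("`voxel_size_um` is required")
  if (volume_basis == "mask") {
    if (is.null(mask)) stop("a tissue mask is required for basis \"mask\"")
    m <- as_mask_array(mask)
    nvox <- sum(m)
    if (nvox == 0) stop("tissue mask is empty; cannot form a mask-based density")
    ref <- nvox * voxel_volume_mm3(voxel_size_um)
  } else {
    shape <- if (!is.null(grid_shape)) {
      grid_shape
    } else if (!is.null(mask)) {
      dim(as_mask_array(mask))
    } else {
      stop("`grid_shape` or `mask` required for basis \"full_fov\"")
    }
    ref <- prod(shape) * voxel_volume_mm3(voxel_size_um)
  }
  structure(
    list(n_cells = nrow(cells), reference_volume_mm3 = ref,
         density_cells_per_mm3 = nrow(cells) / ref,
         volume_basis = volume_basis),
    class = "density_result"
  )
}

#' @export
print.density_result <- function(x, ...) {
  cat(sprintf("<density_result> %d cells / %.4g mm^3 (%s) = %.4g cells/mm^3\n",
              x$n_cells, x$reference_volume_mm3, x$volume_basis,
              x$density_cells_per_mm3))
  invisible(x)
}

#' Match detected cells to ground truth
#'
#' Greedy nearest-neighbour matching: candidate detection-truth pairs
#' within `match_radius_um` are assigned in order of increasing distance,
#' each detection and each truth cell at most once. Precision and recall
#' are defined as 1 when their denominator is empty.
#'
#' @param cells a `cell_table` of detections.
#' @param truth a `ground_truth` table in the same coordinate frame.
#' @param match_radius_um maximum centre distance for a match.
#' @return a `detection_metrics` list: `true_positives`,
#'   `false_positives`, `false_negatives`, `precision`, `recall`, `f1`,
#'   `match_radius_um`.
#' @export
match_to_ground_truth <- function(cells, truth, match_radius_um = 10) {
  stopifnot(inherits(cells, "cell_table"), inherits(truth, "ground_truth"))
  nd <- nrow(cells)
  nt <- nrow(truth)
  tp <- 0L
  if (nd > 0 && nt > 0) {
    dmat <- outer(cells$centroid_x_um, truth$center_x_um, "-")^2 +
      outer(cells$centroid_y_um, truth$center_y_um, "-")^2 +
      outer(cells$centroid_z_um, truth$center_z_um, "-")^2
    cand <- which(dmat <= match_radius_um^2, arr.ind = TRUE)
    if (nrow(cand) > 0) {
      ord <- order(dmat[cand])
      used_d <- logical(nd)
      used_t <- logical(nt)
      for (k in ord) {
        i <- cand[k, 1]; j <- cand[k, 2]
        if (!used_d[i] && !used_t[j]) {
          used_d[i] <- TRUE
          used_t[j] <- TRUE
          tp <- tp + 1L
        }
      }
    }
  }
  fp <- nd - tp
  fn <- nt - tp
  precision <- if (nd == 0) 1 else tp / nd
  recall <- if (nt == 0) 1 else tp / nt
  f1 <- if (precision + recall == 0) 0 else {
    2 * precision * recall / (precision + recall)
  }
  structure(
    list(true_positives = tp, false_positives = fp, false_negatives = fn,
         precision = precision, recall = recall, f1 = f1,
         match_radius_um = match_radius_um),
    class = "detection_metrics"
  )
}

#' Two-sample Student's t test from group summaries
#'
#' Pooled-variance Student's t with `df = n1 + n2 - 2` (the conventional
#' test for small equal groups; Welch's correction available via
#' `welch = TRUE`), computed from group means, standard deviations and
#' sizes.
#'
#' @param mean1,sd1,n1 summary of group 1.
#' @param mean2,sd2,n2 summary of group 2.
#' @param alpha significance level (two-sided).
#' @param welch use Welch's unequal-variance form.
#' @return a `group_comparison`: per-group summaries plus `t`, `df`,
#'   `p_value`, `alpha`, `significant`.
#' @export
ttest_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                               alpha = 0.05, welch = FALSE) {
  if (n1 < 2 || n2 < 2) stop("both groups need n >= 2")
  if (sd1 < 0 || sd2 < 0) stop("standard deviations must be >= 0")
  if (welch) {
    v1 <- sd1^2 / n1
    v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  if (se == 0) {
    if (mean1 == mean2) {
      t <- 0
      p <- 1
    } else {
      stop("zero pooled variance with unequal means: t is infinite")
    }
  } else {
    t <- (mean1 - mean2) / se
    p <- 2 * pt(-abs(t), df)
  }
  structure(
    list(
      group1 = list(mean = mean1, sd = sd1, n = n1),
      group2 = list(mean = mean2, sd = sd2, n = n2),
      t = t, df = df, p_value = p, alpha = alpha,
      significant = is.finite(p) && p < alpha,
      method = if (welch) "welch" else "pooled"
    ),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "<group_comparison> %.4g +/- %.4g (n=%d) vs %.4g +/- %.4g (n=%d)\n",
    x$group1$mean, x$group1$sd, x$group1$n,
    x$group2$mean, x$group2$sd, x$group2$n
  ))
  cat(sprintf("  t = %.4g, df = %.4g, two-sided p = %.4g (%s at alpha = %g)\n",
              x$t, x$df, x$p_value,
              if (x$significant) "significant" else "not significant",
              x$alpha))
  invisible(x)
}

#' Compare two groups of densities
#'
#' Computes per-group mean and sample SD (n - 1 denominator) and applies
#' [ttest_from_summary()].
#'
#' @param densities_a,densities_b numeric vectors (length >= 2).
#' @param alpha significance level.
#' @param welch use Welch's form.
#' @return a `group_comparison`.
#' @export
compare_groups <- function(densities_a, densities_b, alpha = 0.05,
                           welch = FALSE) {
  if (length(densities_a) < 2 || length(densities_b) < 2) {
    stop("each group needs at least 2 values")
  }
  ttest_from_summary(mean(densities_a), sd(densities_a),
                     length(densities_a),
                     mean(densities_b), sd(densities_b),
                     length(densities_b),
                     alpha = alpha, welch = welch)
}
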