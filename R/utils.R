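## Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed`, then restores the
#' caller's RNG state, so seeded operations never perturb an enclosing
#' simulation.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Derive a reproducible per-stage seed from a global seed
#'
#' Hashes the stage name onto the global seed so that every pipeline stage
#' gets its own deterministic RNG stream and can be re-run in isolation.
#'
#' @param global_seed integer global seed.
#' @param stage stage name (character).
#' @return an integer seed in `[0, 2^31)`.
#' @export
stage_seed <- function(global_seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  codes <- utf8ToInt(stage)
  h <- as.double(global_seed) %% 2147483647
  for (k in codes) {
    h <- (h * 31 + k) %% 2147483647
  }
  as.integer(h)
}

## Round half away from zero (documented 8-bit rounding rule; base round()
## rounds half to even).
round_half_up <- function(x) {
  floor(x + 0.5)
}

## clip to a range
clamp <- function(x, lo, hi) {
  pmin(pmax(x, lo), hi)
}

## linear index <-> (x, y, z) voxel index arithmetic (1-based)
index_to_xyz <- function(idx, dims) {
  idx0 <- idx - 1L
  x <- idx0 %% dims[1]
  y <- (idx0 %/% dims[1]) %% dims[2]
  z <- idx0 %/% (dims[1] * dims[2])
  cbind(x = x, y = y, z = z)  # 0-based voxel indices
}

xyz_to_index <- function(x, y, z, dims) {
  1L + x + dims[1] * (y + dims[2] * z)
}
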