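#' Tracking configuration for TEND deterministic tractography
#'
#' Thresholds follow the printed rules of the underlying method: voxels with
#' FA > `seed_fa_threshold` (strict) are seed points; a track terminates in
#' voxels with FA < `stop_fa_threshold` (strict) or when the turn between
#' successive step directions exceeds `max_angle_deg`.
#'
#' @param seed_fa_threshold seed selection threshold, default 0.3.
#' @param stop_fa_threshold termination threshold, default 0.2; must be below
#'   the seed threshold.
#' @param max_angle_deg curvature stop in degrees, default 60.
#' @param step_size_mm step length; default `NULL` means half the smallest
#'   voxel dimension of the tensor field being tracked.
#' @param max_steps per-direction step cap, default 2000.
#' @param seeds_per_voxel seeds per suprathreshold voxel (placed at the voxel
#'   center), default 1.
#' @param f,g tensor-deflection blend weights: the outgoing direction is
#'   `normalize(f * e1 + g * D v_in + (1 - f - g) * v_in)`. Defaults `f = 0`,
#'   `g = 1` give the pure deflection `v_out = normalize(D v_in)`.
#' @return an object of class `tracking_config`.
#' @export
tracking_config <- function(seed_fa_threshold = 0.3,
                            stop_fa_threshold = 0.2,
                            max_angle_deg = 60,
                            step_size_mm = NULL,
                            max_steps = 2000,
                            seeds_per_voxel = 1,
                            f = 0, g = 1) {
  if (stop_fa_threshold >= seed_fa_threshold) {
    stop_validation("stop_fa_threshold must be below seed_fa_threshold")
  }
  if (max_angle_deg <= 0 || max_angle_deg >= 180) {
    stop_validation("max_angle_deg must be in (0, 180)")
  }
  if (!is.null(step_size_mm)) check_positive(step_size_mm, "step_size_mm", 1)
  check_positive(max_steps, "max_steps", 1)
  check_positive(seeds_per_voxel, "seeds_per_voxel", 1)
  structure(list(seed_fa_threshold = seed_fa_threshold,
                 stop_fa_threshold = stop_fa_threshold,
                 max_angle_deg = max_angle_deg,
                 step_size_mm = step_size_mm,
                 max_steps = as.integer(max_steps),
                 seeds_per_voxel = as.integer(seeds_per_voxel),
                 f = f, g = g),
            class = "tracking_config")
}

#' Tractogram container
#'
#' @param streamlines list of streamlines; each is a list with `points`
#'   (n x 3 matrix, world mm), `seed_voxel` (0-based integer triple) and
#'   `termination_reasons` (character pair for the two launch directions).
#' @param affine reference voxel-to-mm affine.
#' @param grid_shape reference grid dimensions.
#' @return an object of class `tractogram`.
#' @export
tractogram <- function(streamlines, affine, grid_shape) {
  structure(list(streamlines = streamlines, affine = affine,
                 grid_shape = as.integer(grid_shape)),
            class = "tractogram")
}

#' @export
print.tractogram <- function(x, ...) {
  reasons <- unlist(lapply(x$streamlines, `[[`, "termination_reasons"))
  cat(sprintf("tractogram: %d streamlines on a %s grid\n",
              length(x$streamlines), paste(x$grid_shape, collapse = "x")))
  if (length(reasons)) print(table(reasons))
  invisible(x)
}

#' Select tracking seed voxels
#'
#' Exactly the voxels with FA strictly above the seed threshold, each
#' contributing `seeds_per_voxel` seed points at the voxel center.
#'
#' @param field a [tensor_field()].
#' @param config a [tracking_config()].
#' @return integer matrix of 0-based seed voxel indices (one row per seed).
#' @export
select_seeds <- function(field, config = tracking_config()) {
  stopifnot(inherits(field, "tensor_field"))
  sel <- which(field$fa > config$seed_fa_threshold & field$valid, arr.ind = TRUE) - 1L
  if (nrow(sel) == 0) {
    warning("no voxels exceed the seed FA threshold; tractogram will be empty")
  }
  sel <- sel[rep(seq_len(nrow(sel)), each = config$seeds_per_voxel), , drop = FALSE]
  colnames(sel) <- c("i", "j", "k")
  sel
}

# fetch (fa, d6 row, validity) at a world point by nearest-voxel lookup
field_at <- function(field, point, inv_affine) {
  h <- inv_affine %*% c(point, 1)
  vox <- floor(h[1:3] + 0.5)
  if (any(vox < 0) || any(vox >= field$grid_shape)) return(NULL)
  i <- vox + 1L
  list(fa = field$fa[i[1], i[2], i[3]],
       d6 = field$d6[i[1], i[2], i[3], ],
       e1 = field$e1[i[1], i[2], i[3], ],
       valid = field$valid[i[1], i[2], i[3]])
}

# One half-track from `start` along initial direction v0. Points are only
# appended after passing the bounds and FA checks, so every retained point
# lies inside the grid in a voxel at or above the stop threshold; the
# terminating voxel/position itself is not part of the streamline.
half_track <- function(field, start, v0, config, step, inv_affine, cos_limit) {
  pts <- matrix(0, config$max_steps + 1L, 3)
  pts[1, ] <- start
  n_pts <- 1L
  v_in <- v0
  reason <- "max_steps"
  repeat {
    if (n_pts - 1L >= config$max_steps) { reason <- "max_steps"; break }
    cur <- field_at(field, pts[n_pts, ], inv_affine)
    D <- d6_to_matrix(cur$d6)
    v_out <- config$f * cur$e1 + config$g * as.numeric(D %*% v_in) +
      (1 - config$f - config$g) * v_in
    nrm <- sqrt(sum(v_out^2))
    if (nrm < 1e-30) { reason <- "low_fa"; break }  # zero tensor
    v_out <- v_out / nrm
    if (sum(v_out * v_in) < 0) v_out <- -v_out
    if (sum(v_out * v_in) < cos_limit) { reason <- "curvature"; break }
    candidate <- pts[n_pts, ] + step * v_out
    nxt <- field_at(field, candidate, inv_affine)
    if (is.null(nxt)) { reason <- "out_of_bounds"; break }
    if (!nxt$valid || nxt$fa < config$stop_fa_threshold) { reason <- "low_fa"; break }
    n_pts <- n_pts + 1L
    pts[n_pts, ] <- candidate
    v_in <- v_out
  }
  list(points = pts[seq_len(n_pts), , drop = FALSE], reason = reason)
}

#' Propagate a single TEND streamline from a seed voxel
#'
#' Two half-tracks are launched from the seed voxel center along +e1 and -e1
#' of the seed tensor. At each step the incoming unit direction `v_in` is
#' deflected by the full local tensor, `v_out = normalize(D v_in)` (optionally
#' blended with `e1` and `v_in` via the `f`, `g` weights), with the sign
#' chosen so `v_out . v_in >= 0`; the next point is one step along `v_out`.
#' A half-track terminates on low FA, a turn above the curvature limit,
#' leaving the grid, or the step cap. The streamline is the reversed second
#' half-track concatenated with the first; the junction between the two
#' half-tracks is exempt from the curvature test (they launch at 180 degrees
#' by design).
#'
#' @param field a [tensor_field()].
#' @param seed_voxel 0-based integer voxel triple.
#' @param config a [tracking_config()].
#' @return a streamline: list with `points` (n x 3, world mm), `seed_voxel`,
#'   `termination_reasons` (reasons for the +e1 and -e1 half-tracks).
#' @export
propagate <- function(field, seed_voxel, config = tracking_config()) {
  stopifnot(inherits(field, "tensor_field"))
  seed_voxel <- as.integer(seed_voxel)
  if (any(seed_voxel < 0) || any(seed_voxel >= field$grid_shape)) {
    stop_validation("seed voxel outside the grid")
  }
  step <- if (is.null(config$step_size_mm)) min(field$voxel_size_mm) / 2 else config$step_size_mm
  inv_affine <- affine_inverse(field$affine)
  start <- as.numeric(voxel_to_world(matrix(seed_voxel, 1), field$affine))
  i <- seed_voxel + 1L
  e1 <- field$e1[i[1], i[2], i[3], ]
  cos_limit <- cos(config$max_angle_deg * pi / 180)
  if (!field$valid[i[1], i[2], i[3]] ||
      field$fa[i[1], i[2], i[3]] < config$stop_fa_threshold) {
    return(list(points = matrix(start, 1), seed_voxel = seed_voxel,
                termination_reasons = c("low_fa", "low_fa"),
                junction_index = 1L))
  }
  fwd <- half_track(field, start, e1, config, step, inv_affine, cos_limit)
  bwd <- half_track(field, start, -e1, config, step, inv_affine, cos_limit)
  pts <- rbind(bwd$points[rev(seq_len(nrow(bwd$points))[-1]), , drop = FALSE],
               fwd$points)
  list(points = pts, seed_voxel = seed_voxel,
       termination_reasons = c(fwd$reason, bwd$reason),
       junction_index = nrow(bwd$points))
}

#' Whole-volume deterministic tractography
#'
#' One streamline per seed from [select_seeds()]; fully deterministic (no
#' randomness anywhere in tracking). Streamlines reduced to a single point
#' (immediate termination in both directions) are kept, so `n_all` downstream
#' counts every launched seed.
#'
#' @param field a [tensor_field()].
#' @param config a [tracking_config()].
#' @return a [tractogram()].
#' @export
track_whole_volume <- function(field, config = tracking_config()) {
  seeds <- select_seeds(field, config)
  streamlines <- vector("list", nrow(seeds))
  for (s in seq_len(nrow(seeds))) {
    streamlines[[s]] <- propagate(field, seeds[s, ], config)
  }
  tractogram(streamlines, field$affine, field$grid_shape)
}

#' Termination-reason histogram of a tractogram
#'
#' @param tract a [tractogram()].
#' @return named integer vector over termination reasons (both directions).
#' @export
termination_summary <- function(tract) {
  stopifnot(inherits(tract, "tractogram"))
  reasons <- unlist(lapply(tract$streamlines, `[[`, "termination_reasons"))
  table(factor(reasons, levels = c("low_fa", "curvature", "out_of_bounds", "max_steps")))
}
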