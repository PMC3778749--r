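#' Threshold a probabilistic atlas into an integer label volume
#'
#' A voxel receives the label of the region with the highest probability among
#' regions whose probability strictly exceeds the threshold, and 0 (background)
#' when no region passes. Assigning by argmax-above-threshold guarantees
#' non-overlapping regions; exact probability ties are broken toward the
#' lowest region index, deterministically. Probabilities may be given in
#' percent (`[0, 100]`) or as fractions (`[0, 1]`); the scale is auto-detected
#' from the array maximum.
#'
#' @param prob_atlas 4-D array (x, y, z, region) of R probability maps.
#' @param threshold_pct inclusion threshold in percent, default 35.
#' @param voxel_size_mm,affine grid geometry of the atlas.
#' @param region_names optional names for the R regions.
#' @return a [label_volume()].
#' @export
threshold_probabilistic_atlas <- function(prob_atlas, threshold_pct = 35,
                                          voxel_size_mm = c(1, 1, 1),
                                          affine = NULL, region_names = NULL) {
  dm <- dim(prob_atlas)
  if (length(dm) != 4 || dm[4] < 1) {
    stop_validation("prob_atlas must be a 4-D array with at least one region map")
  }
  if (threshold_pct < 0 || threshold_pct > 100) {
    stop_validation("threshold_pct must be in [0, 100]")
  }
  r <- dm[4]
  p <- matrix(prob_atlas, prod(dm[1:3]), r)
  if (any(p < 0)) stop_validation("probabilities must be non-negative")
  mx <- max(p)
  thr <- if (mx <= 1 + 1e-9) threshold_pct / 100 else threshold_pct
  if (mx > 1 + 1e-9 && mx > 100 + 1e-9) {
    stop_validation("probabilities exceed 100: not a percent or fraction scale")
  }
  pass <- p > thr
  p[!pass] <- -Inf
  lab <- max.col(p, ties.method = "first")
  lab[rowSums(pass) == 0] <- 0L
  label_volume(array(lab, dm[1:3]), voxel_size_mm, affine, region_names)
}

#' Resample an integer label volume through an affine transform
#'
#' Nearest-neighbor resampling of labels onto a target grid: each target voxel
#' center is mapped through the template-to-native transform's inverse into
#' the atlas grid and takes the label of the nearest source voxel (0 outside).
#' Labels are never interpolated, so the label set can only shrink.
#'
#' @param atlas a [label_volume()] (template space).
#' @param transform an [affine_transform()] between template and native voxel
#'   grids (voxel-to-voxel); a `native_to_template` matrix is inverted.
#' @param target_shape integer triple: native grid dimensions.
#' @param target_voxel_size_mm,target_affine native grid geometry (defaults to
#'   scaling by the voxel size).
#' @return a [label_volume()] on the target grid.
#' @export
resample_labels <- function(atlas, transform, target_shape,
                            target_voxel_size_mm = atlas$voxel_size_mm,
                            target_affine = NULL) {
  stopifnot(inherits(atlas, "label_volume"), inherits(transform, "affine_transform"))
  target_shape <- as.integer(target_shape)
  check_positive(target_shape, "target_shape", 3)
  # native voxel -> template voxel mapping
  m <- transform$matrix
  if (transform$direction == "template_to_native") m <- solve(m)
  tgt_idx <- as.matrix(expand.grid(x = 0:(target_shape[1] - 1),
                                   y = 0:(target_shape[2] - 1),
                                   z = 0:(target_shape[3] - 1)))
  src <- cbind(tgt_idx, 1) %*% t(m)
  src_vox <- floor(src[, 1:3, drop = FALSE] + 0.5)
  ok <- in_grid(src_vox, dim(atlas$labels))
  lab <- integer(nrow(tgt_idx))
  lab[ok] <- atlas$labels[src_vox[ok, , drop = FALSE] + 1L]
  label_volume(array(lab, target_shape), target_voxel_size_mm, target_affine,
               atlas$region_names)
}
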