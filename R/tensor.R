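#' Fractional anisotropy from tensor eigenvalues
#'
#' FA = sqrt(1/2) * sqrt((l1-l2)^2 + (l2-l3)^2 + (l3-l1)^2) / sqrt(l1^2+l2^2+l3^2),
#' the normalized dispersion of the eigenvalues: 0 for isotropic diffusion,
#' 1 in the one-dimensional limit. All-zero eigenvalues define FA = 0 so that
#' empty voxels never inject NaN into tracking masks.
#'
#' @param eigenvalues numeric vector of 3 non-negative eigenvalues, or a
#'   matrix with one row per voxel and 3 columns.
#' @return FA value(s) in `[0, 1]`.
#' @export
fa_of <- function(eigenvalues) {
  ev <- if (is.matrix(eigenvalues)) eigenvalues else matrix(eigenvalues, ncol = 3)
  if (ncol(ev) != 3) stop_validation("eigenvalues must have 3 components")
  if (any(ev < -1e-12)) stop_validation("negative eigenvalue beyond tolerance")
  ev[ev < 0] <- 0
  num <- (ev[, 1] - ev[, 2])^2 + (ev[, 2] - ev[, 3])^2 + (ev[, 3] - ev[, 1])^2
  den <- rowSums(ev^2)
  fa <- sqrt(0.5) * sqrt(num / pmax(den, .Machine$double.xmin))
  fa[den == 0] <- 0
  fa <- pmin(pmax(fa, 0), 1)
  if (is.matrix(eigenvalues)) fa else as.numeric(fa)
}

#' Mean diffusivity from tensor eigenvalues
#'
#' MD = (l1 + l2 + l3) / 3, in mm^2/s.
#'
#' @inheritParams fa_of
#' @return MD value(s), non-negative.
#' @export
md_of <- function(eigenvalues) {
  ev <- if (is.matrix(eigenvalues)) eigenvalues else matrix(eigenvalues, ncol = 3)
  if (ncol(ev) != 3) stop_validation("eigenvalues must have 3 components")
  if (any(ev < -1e-12)) stop_validation("negative eigenvalue beyond tolerance")
  ev[ev < 0] <- 0
  md <- rowMeans(ev)
  if (is.matrix(eigenvalues)) md else as.numeric(md)
}

# 6-component tensor rows (Dxx, Dxy, Dxz, Dyy, Dyz, Dzz) -> 3x3 matrix
d6_to_matrix <- function(d6) {
  matrix(c(d6[1], d6[2], d6[3],
           d6[2], d6[4], d6[5],
           d6[3], d6[5], d6[6]), 3, 3)
}

matrix_to_d6 <- function(D) c(D[1, 1], D[1, 2], D[1, 3], D[2, 2], D[2, 3], D[3, 3])

# per-voxel eigen-decomposition of a V x 6 tensor table; eigenvalues are
# clamped at 0 for FA/MD, negativity recorded in `valid`
tensor_derived <- function(d6, compute_mask = NULL) {
  v <- nrow(d6)
  if (is.null(compute_mask)) compute_mask <- rep(TRUE, v)
  evals <- matrix(0, v, 3)
  e1 <- matrix(0, v, 3)
  valid <- compute_mask
  for (i in which(compute_mask)) {
    eg <- eigen(d6_to_matrix(d6[i, ]), symmetric = TRUE)
    evals[i, ] <- eg$values
    e1[i, ] <- eg$vectors[, 1]
  }
  # negative eigenvalues (noise) are clamped for FA/MD and flagged, but the
  # clamped tensor remains usable -- negativity does not invalidate the voxel
  neg <- evals[, 3] < -1e-12 & compute_mask
  evals[evals < 0] <- 0
  fa <- rep(0, v)
  md <- rep(0, v)
  fa[compute_mask] <- fa_of(evals[compute_mask, , drop = FALSE])
  md[compute_mask] <- md_of(evals[compute_mask, , drop = FALSE])
  list(eigenvalues = evals, e1 = e1, fa = fa, md = md, valid = valid,
       negative_ev = neg)
}

#' Construct a tensor field from per-voxel tensor components
#'
#' @param d6 4-D array (x, y, z, 6) of tensor components in the order
#'   Dxx, Dxy, Dxz, Dyy, Dyz, Dzz (mm^2/s).
#' @param voxel_size_mm 3 positive reals.
#' @param affine 4x4 voxel-to-mm matrix.
#' @param mask optional logical 3-D array of voxels that carry a tensor.
#' @return an object of class `tensor_field` with elements `d6`, `fa`, `md`,
#'   `e1` (x, y, z, 3), `eigenvalues` (x, y, z, 3, descending), `valid`,
#'   `affine`, `voxel_size_mm`, `grid_shape`.
#' @export
tensor_field <- function(d6, voxel_size_mm, affine = NULL, mask = NULL) {
  dm <- dim(d6)
  if (length(dm) != 4 || dm[4] != 6) stop_validation("d6 must be (x, y, z, 6)")
  shape <- dm[1:3]
  check_positive(voxel_size_mm, "voxel_size_mm", 3)
  if (is.null(affine)) affine <- diag(c(voxel_size_mm, 1))
  v <- prod(shape)
  flat <- matrix(d6, v, 6)
  m <- if (is.null(mask)) rep(TRUE, v) else as.logical(mask)
  der <- tensor_derived(flat, m)
  structure(list(
    d6 = d6,
    fa = array(der$fa, shape),
    md = array(der$md, shape),
    e1 = array(der$e1, c(shape, 3)),
    eigenvalues = array(der$eigenvalues, c(shape, 3)),
    valid = array(der$valid, shape),
    negative_ev = array(der$negative_ev, shape),
    affine = affine,
    voxel_size_mm = as.numeric(voxel_size_mm),
    grid_shape = shape
  ), class = "tensor_field")
}

#' @export
print.tensor_field <- function(x, ...) {
  cat(sprintf("tensor_field: %s grid, %d valid voxels, FA range [%.3f, %.3f]\n",
              paste(x$grid_shape, collapse = "x"), sum(x$valid),
              min(x$fa), max(x$fa)))
  invisible(x)
}

#' Fit the diffusion tensor voxel-wise by log-linear least squares
#'
#' Solves the log-linearized Stejskal-Tanner system
#' `log(S_k) = log(S_0) - b_k g_k' D g_k` by ordinary least squares over the
#' six unique tensor elements plus the log baseline, per voxel. Multiple b = 0
#' volumes are averaged into a single baseline before fitting. Voxels with any
#' non-positive signal are flagged invalid and carry a zero tensor; negative
#' eigenvalues are clamped at zero for FA/MD and flagged.
#'
#' @param dwi a [dwi_volume()].
#' @param gradients a [gradient_table()] matching the 4th data dimension.
#' @param mask optional logical 3-D array restricting the fit.
#' @return a [tensor_field()].
#' @export
fit_tensor <- function(dwi, gradients, mask = NULL) {
  stopifnot(inherits(dwi, "dwi_volume"), inherits(gradients, "gradient_table"))
  dm <- dim(dwi$data)
  if (dm[4] != length(gradients$bvals)) {
    stop_validation("gradient table length does not match DWI 4th dimension")
  }
  shape <- dm[1:3]
  v <- prod(shape)
  sig <- matrix(dwi$data, v, dm[4])

  b0_idx <- which(gradients$bvals == 0)
  dw_idx <- which(gradients$bvals > 0)
  s0 <- if (length(b0_idx) > 1) rowMeans(sig[, b0_idx, drop = FALSE]) else sig[, b0_idx]

  b <- gradients$bvals[dw_idx]
  g <- gradients$bvecs[dw_idx, , drop = FALSE]
  # design for the 6 tensor elements + intercept (log S0)
  X <- cbind(-b * g[, 1]^2, -2 * b * g[, 1] * g[, 2], -2 * b * g[, 1] * g[, 3],
             -b * g[, 2]^2, -2 * b * g[, 2] * g[, 3], -b * g[, 3]^2, 1)
  # one averaged baseline row at b = 0
  X <- rbind(X, c(0, 0, 0, 0, 0, 0, 1))
  if (qr(X)$rank < 7) stop_config("rank-deficient gradient design: directions do not span 3-space")

  fit_mask <- if (is.null(mask)) rep(TRUE, v) else as.logical(mask)
  ok <- fit_mask & s0 > 0 &
    rowSums(sig[, dw_idx, drop = FALSE] <= 0) == 0
  y <- cbind(sig[, dw_idx, drop = FALSE], s0)
  y[!ok, ] <- 1  # placeholder; rows are zeroed after the solve
  coef <- solve(crossprod(X), crossprod(X, t(log(y))))  # 7 x V
  d6 <- t(coef[1:6, , drop = FALSE])
  d6[!ok, ] <- 0

  field <- tensor_field(array(d6, c(shape, 6)), dwi$voxel_size_mm, dwi$affine,
                        mask = array(ok, shape))
  field$valid <- field$valid & array(ok, shape)
  field
}

#' Write tensor-field maps as NIfTI-1 volumes
#'
#' Writes `fa.nii.gz`, `md.nii.gz`, `e1.nii.gz` (3-vector volume) and
#' `tensor.nii.gz` (6 components, lower-triangular FSL order).
#'
#' @param field a [tensor_field()].
#' @param dir output directory (created if needed).
#' @return invisibly, the output paths.
#' @export
write_tensor_field <- function(field, dir) {
  stopifnot(inherits(field, "tensor_field"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("fa.nii.gz", "md.nii.gz", "e1.nii.gz", "tensor.nii.gz"))
  write_nifti(field$fa, paths[1], field$affine)
  write_nifti(field$md, paths[2], field$affine)
  write_nifti(field$e1, paths[3], field$affine)
  write_nifti(field$d6, paths[4], field$affine)
  invisible(paths)
}
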