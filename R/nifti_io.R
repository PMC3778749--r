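#' Image containers and NIfTI-1 I/O
#'
#' Volumes are plain R arrays plus a 4x4 voxel-to-world affine in the NIfTI
#' convention: the affine maps 0-based voxel indices to world mm (RAS) at the
#' voxel center, so voxel `i` occupies the half-open world cell corresponding
#' to continuous indices `[i - 0.5, i + 0.5)` and point-to-voxel lookup is
#' `floor(index + 0.5)`.
#'
#' @name nifti-io
NULL

#' Construct a 4-D diffusion-weighted volume
#'
#' @param data 4-D numeric array (x, y, z, gradient) of non-negative signals.
#' @param affine 4x4 voxel-to-mm matrix (default: scaling by `voxel_size_mm`).
#' @param voxel_size_mm 3 positive voxel edge lengths in mm.
#' @return an object of class `dwi_volume`.
#' @export
dwi_volume <- function(data, voxel_size_mm, affine = NULL) {
  if (length(dim(data)) != 4) stop_validation("DWI data must be a 4-D array")
  if (any(data < 0, na.rm = TRUE)) stop_validation("DWI signals must be non-negative")
  check_positive(voxel_size_mm, "voxel_size_mm", 3)
  if (is.null(affine)) affine <- diag(c(voxel_size_mm, 1))
  stopifnot(all(dim(affine) == c(4, 4)))
  structure(list(data = data, affine = affine,
                 voxel_size_mm = as.numeric(voxel_size_mm)),
            class = "dwi_volume")
}

#' Construct an integer region-label volume
#'
#' @param labels 3-D integer array; 0 is background, 1..R are regions.
#' @param region_names character vector naming regions 1..R (default `"region_<k>"`).
#' @param affine 4x4 voxel-to-mm matrix.
#' @param voxel_size_mm 3 positive reals.
#' @return an object of class `label_volume`.
#' @export
label_volume <- function(labels, voxel_size_mm, affine = NULL,
                         region_names = NULL) {
  if (length(dim(labels)) != 3) stop_validation("labels must be a 3-D array")
  storage.mode(labels) <- "integer"
  if (any(labels < 0, na.rm = TRUE)) stop_validation("labels must be >= 0")
  check_positive(voxel_size_mm, "voxel_size_mm", 3)
  if (is.null(affine)) affine <- diag(c(voxel_size_mm, 1))
  r <- max(0L, max(labels))
  if (is.null(region_names)) region_names <- paste0("region_", seq_len(r))
  if (length(region_names) < r) stop_validation("fewer region names than region ids")
  structure(list(labels = labels, region_names = region_names,
                 affine = affine, voxel_size_mm = as.numeric(voxel_size_mm)),
            class = "label_volume")
}

# inverse of a voxel->mm affine, validated
affine_inverse <- function(affine) {
  if (abs(det(affine)) < 1e-12) stop_validation("singular affine matrix")
  solve(affine)
}

# world mm points (n x 3) -> continuous 0-based voxel indices (n x 3)
world_to_voxel_continuous <- function(points, affine) {
  points <- matrix(points, ncol = 3)
  inv <- affine_inverse(affine)
  h <- cbind(points, 1) %*% t(inv)
  h[, 1:3, drop = FALSE]
}

# world mm points -> 0-based integer voxel indices (nearest voxel, floor(c+0.5))
world_to_voxel_index <- function(points, affine) {
  cont <- world_to_voxel_continuous(points, affine)
  storage.mode(cont) <- "double"
  floor(cont + 0.5)
}

# 0-based voxel indices (n x 3) -> world mm at voxel centers
voxel_to_world <- function(index, affine) {
  index <- matrix(index, ncol = 3)
  h <- cbind(index, 1) %*% t(affine)
  h[, 1:3, drop = FALSE]
}

in_grid <- function(index, grid_shape) {
  index[, 1] >= 0 & index[, 1] < grid_shape[1] &
    index[, 2] >= 0 & index[, 2] < grid_shape[2] &
    index[, 3] >= 0 & index[, 3] < grid_shape[3]
}

#' Write an array as NIfTI-1
#'
#' @param data 3-D or 4-D numeric array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param affine 4x4 voxel-to-mm matrix.
#' @return invisibly, `path`.
#' @export
write_nifti <- function(data, path, affine) {
  img <- RNifti::asNifti(data)
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::pixdim(img) <- sqrt(colSums(affine[1:3, 1:3]^2))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI-1 volume as a plain array plus affine
#'
#' @param path path to a `.nii`/`.nii.gz` file.
#' @return list with `data` (array), `affine` (4x4), `voxel_size_mm`.
#' @export
read_nifti_array <- function(path) {
  if (!file.exists(path)) stop_parse(paste("missing NIfTI file:", path))
  img <- RNifti::readNifti(path)
  affine <- matrix(as.numeric(unclass(RNifti::xform(img))), 4, 4)
  list(data = array(as.numeric(img), dim = dim(img)),
       affine = affine,
       voxel_size_mm = sqrt(colSums(affine[1:3, 1:3]^2)))
}

#' Read a 4-D DWI NIfTI together with its gradient table
#'
#' @param dwi_path NIfTI path.
#' @param bval_path,bvec_path FSL gradient files.
#' @return list with `dwi` ([dwi_volume()]) and `gradients` ([gradient_table()]).
#' @export
read_dwi <- function(dwi_path, bval_path, bvec_path) {
  raw <- read_nifti_array(dwi_path)
  if (length(dim(raw$data)) != 4) stop_validation("DWI NIfTI must be 4-D")
  gradients <- read_gradients(bval_path, bvec_path)
  if (dim(raw$data)[4] != length(gradients$bvals)) {
    stop_validation(sprintf("DWI has %d volumes but gradient table has %d entries",
                            dim(raw$data)[4], length(gradients$bvals)))
  }
  list(dwi = dwi_volume(raw$data, raw$voxel_size_mm, raw$affine),
       gradients = gradients)
}

#' Read an integer label NIfTI
#'
#' @param path NIfTI path.
#' @param region_names optional character vector of region names.
#' @return a [label_volume()].
#' @export
read_labels <- function(path, region_names = NULL) {
  raw <- read_nifti_array(path)
  label_volume(round(raw$data), raw$voxel_size_mm, raw$affine, region_names)
}

#' Read a 4x4 affine transform in FSL FLIRT text format
#'
#' @param path text file with four whitespace-separated rows of four numbers.
#' @param direction `"template_to_native"` or `"native_to_template"`.
#' @return an object of class `affine_transform` (`matrix`, `direction`).
#' @export
read_affine <- function(path, direction = c("template_to_native", "native_to_template")) {
  direction <- match.arg(direction)
  m <- as.matrix(read.table(path))
  if (!all(dim(m) == c(4, 4))) {
    stop_parse(sprintf("affine file '%s' is not a 4x4 matrix", path))
  }
  affine_transform(m, direction)
}

#' Construct an affine transform with a declared direction
#'
#' @param matrix invertible 4x4 matrix.
#' @param direction which way the matrix maps.
#' @return an `affine_transform` object.
#' @export
affine_transform <- function(matrix, direction = c("template_to_native", "native_to_template")) {
  direction <- match.arg(direction)
  matrix <- as.matrix(matrix)
  stopifnot(all(dim(matrix) == c(4, 4)))
  if (abs(det(matrix)) < 1e-12) stop_validation("affine transform is singular")
  structure(list(matrix = unname(matrix), direction = direction),
            class = "affine_transform")
}
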