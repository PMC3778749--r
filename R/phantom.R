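#' Specification of a synthetic fiber-bundle DWI phantom
#'
#' Describes a single fiber bundle embedded in an otherwise near-isotropic
#' volume. Inside the bundle the diffusion tensor is cigar-shaped and oriented
#' along the local bundle tangent; outside it is low-anisotropy so that
#' tracking can neither seed nor continue there. The two bundle end-caps are
#' labeled as regions 1 and 2, giving every phantom a known ground-truth
#' connection.
#'
#' @param grid_shape 3 positive integers (voxels).
#' @param voxel_size_mm 3 positive reals (mm).
#' @param geometry one of `"straight"`, `"arc"`, `"sharp_bend"`, `"crossing"`.
#' @param bundle_radius_vox bundle radius in voxel units of the smallest voxel
#'   dimension.
#' @param inside_eigenvalues descending tensor eigenvalues inside the bundle
#'   (mm^2/s); must give FA > 0.3 so the bundle is seedable.
#' @param outside_eigenvalues descending eigenvalues outside (mm^2/s); must
#'   give FA < 0.2 so tracking stops there.
#' @param arc_angle_deg total turning angle for `arc`/`sharp_bend` geometries,
#'   in (0, 180]. An arc spreads the turn smoothly (every per-step turn stays
#'   far below the 60 degree stop rule); a sharp bend concentrates it at
#'   mid-bundle to exercise the curvature stop.
#' @param s0 baseline (b = 0) signal.
#' @param snr signal-to-noise ratio for Rician noise, or `NULL` for a
#'   noiseless phantom.
#' @param cap_length_vox end-cap region depth along the bundle, in voxels.
#' @param seed integer seed used only when `snr` is set.
#' @return an object of class `bundle_phantom_spec`.
#' @export
bundle_phantom_spec <- function(grid_shape = c(40, 20, 20),
                                voxel_size_mm = c(2, 2, 2),
                                geometry = c("straight", "arc", "sharp_bend", "crossing"),
                                bundle_radius_vox = 3.5,
                                inside_eigenvalues = c(1.7e-3, 3e-4, 3e-4),
                                outside_eigenvalues = c(1.0e-3, 0.9e-3, 0.9e-3),
                                arc_angle_deg = NULL,
                                s0 = 1000,
                                snr = NULL,
                                cap_length_vox = 3,
                                seed = 1L) {
  geometry <- match.arg(geometry)
  # Pure tensor deflection turns an incoming direction by at most
  # 90 - 2*atan(sqrt(l2/l1)) degrees in a single step, whatever the bend
  # angle. For the sharp-bend phantom to place a > 60 degree turn at the bend
  # (its whole purpose), the in-bundle tensor must be prolate enough:
  # l2/l1 < tan(15 deg)^2 ~ 0.072. The default bend tensor uses l2/l1 = 0.035.
  if (geometry == "sharp_bend" && missing(inside_eigenvalues)) {
    inside_eigenvalues <- c(1.7e-3, 6e-5, 6e-5)
  }
  check_positive(grid_shape, "grid_shape", 3)
  check_positive(voxel_size_mm, "voxel_size_mm", 3)
  check_positive(bundle_radius_vox, "bundle_radius_vox", 1)
  check_positive(inside_eigenvalues, "inside_eigenvalues", 3)
  check_positive(outside_eigenvalues, "outside_eigenvalues", 3)
  check_positive(s0, "s0", 1)
  check_positive(cap_length_vox, "cap_length_vox", 1)
  if (!is.null(snr)) check_positive(snr, "snr", 1)
  if (is.unsorted(rev(inside_eigenvalues)) || is.unsorted(rev(outside_eigenvalues))) {
    stop_validation("eigenvalues must be in descending order")
  }
  if (is.null(arc_angle_deg)) {
    arc_angle_deg <- switch(geometry, arc = 45, sharp_bend = 80, 0)
  }
  if (geometry %in% c("arc", "sharp_bend") &&
      (arc_angle_deg <= 0 || arc_angle_deg > 180)) {
    stop_validation("arc_angle_deg must be in (0, 180]")
  }
  fa_in <- fa_of(inside_eigenvalues)
  fa_out <- fa_of(outside_eigenvalues)
  if (fa_in <= 0.3) stop_validation(sprintf(
    "inside eigenvalues give FA = %.3f; must exceed the 0.3 seed threshold", fa_in))
  if (fa_out >= 0.2) stop_validation(sprintf(
    "outside eigenvalues give FA = %.3f; must be below the 0.2 stop threshold", fa_out))
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size_mm = as.numeric(voxel_size_mm),
                 geometry = geometry,
                 bundle_radius_vox = bundle_radius_vox,
                 inside_eigenvalues = as.numeric(inside_eigenvalues),
                 outside_eigenvalues = as.numeric(outside_eigenvalues),
                 arc_angle_deg = arc_angle_deg,
                 s0 = s0, snr = snr,
                 cap_length_vox = cap_length_vox,
                 seed = as.integer(seed)),
            class = "bundle_phantom_spec")
}

# orthonormal basis with first column t (unit)
complete_basis <- function(t) {
  t <- t / sqrt(sum(t^2))
  ref <- if (abs(t[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  n1 <- ref - sum(ref * t) * t
  n1 <- n1 / sqrt(sum(n1^2))
  n2 <- c(t[2] * n1[3] - t[3] * n1[2],
          t[3] * n1[1] - t[1] * n1[3],
          t[1] * n1[2] - t[2] * n1[1])
  cbind(t, n1, n2)
}

# tensor with eigenvalues `ev` (descending) and principal axis `t`, as d6 row
oriented_tensor_d6 <- function(t, ev) {
  R <- complete_basis(t)
  matrix_to_d6(R %*% diag(ev) %*% t(R))
}

# distance from points (n x 3, mm) to a segment [a, b]; returns distance,
# arclength along the segment from a, and the (constant) tangent
dist_to_segment <- function(p, a, b) {
  ab <- b - a
  len <- sqrt(sum(ab^2))
  u <- ab / len
  ap <- sweep(p, 2, a)
  t_raw <- as.numeric(ap %*% u)
  t_cl <- pmin(pmax(t_raw, 0), len)
  foot <- outer(t_cl, u) + matrix(a, nrow(p), 3, byrow = TRUE)
  d <- sqrt(rowSums((p - foot)^2))
  list(dist = d, s = t_cl, tangent = u, len = len)
}

# centerline description for each geometry: voxel centers -> per-voxel
# distance to the bundle axis, arclength position s (mm), tangent (n x 3)
bundle_geometry <- function(spec, centers) {
  vs <- spec$voxel_size_mm
  ext <- spec$grid_shape * vs          # grid extent, mm
  mid <- (spec$grid_shape - 1) / 2 * vs
  margin <- 1.5 * max(vs)
  n <- nrow(centers)
  tangent <- matrix(0, n, 3)

  if (spec$geometry %in% c("straight", "crossing")) {
    a <- c(margin, mid[2], mid[3]); b <- c(ext[1] - vs[1] - margin, mid[2], mid[3])
    if (b[1] - a[1] < 4 * max(vs)) stop_config("grid too small for the bundle geometry")
    seg <- dist_to_segment(centers, a, b)
    dist <- seg$dist; s <- seg$s; total <- seg$len
    tangent[] <- matrix(seg$tangent, n, 3, byrow = TRUE)
    out <- list(dist = dist, s = s, total_len = total, tangent = tangent)
    if (spec$geometry == "crossing") {
      a2 <- c(mid[1], margin, mid[3]); b2 <- c(mid[1], ext[2] - vs[2] - margin, mid[3])
      if (b2[2] - a2[2] < 4 * max(vs)) stop_config("grid too small for the crossing bundle")
      seg2 <- dist_to_segment(centers, a2, b2)
      out$second <- list(dist = seg2$dist, s = seg2$s, total_len = seg2$len,
                         tangent = matrix(seg2$tangent, n, 3, byrow = TRUE))
    }
    return(out)
  }

  if (spec$geometry == "sharp_bend") {
    # two straight half-segments meeting at grid center, turning by arc_angle
    ang <- spec$arc_angle_deg * pi / 180
    u1 <- c(1, 0, 0)
    u2 <- c(cos(ang), sin(ang), 0)
    half <- min(ext[1], ext[2]) / 2 - margin - max(vs)
    if (half < 3 * max(vs)) stop_config("grid too small for the sharp-bend geometry")
    ctr <- mid
    a <- ctr - half * u1
    b2 <- ctr + half * u2
    s1 <- dist_to_segment(centers, a, ctr)
    s2 <- dist_to_segment(centers, ctr, b2)
    use2 <- s2$dist < s1$dist
    dist <- ifelse(use2, s2$dist, s1$dist)
    s <- ifelse(use2, half + s2$s, s1$s)
    tangent <- matrix(u1, n, 3, byrow = TRUE)
    tangent[use2, ] <- matrix(u2, sum(use2), 3, byrow = TRUE)
    return(list(dist = dist, s = s, total_len = 2 * half, tangent = tangent))
  }

  # arc: circular arc of total turn arc_angle in the x-y plane
  ang <- spec$arc_angle_deg * pi / 180
  chord_fit <- min(ext[1], ext[2]) - 2 * (margin + max(vs))
  # radius chosen so the chord of the arc fits the grid
  radius <- chord_fit / (2 * sin(ang / 2))
  ctr2 <- c(mid[1], mid[2] - radius * cos(ang / 2), mid[3])
  phi0 <- pi / 2 - ang / 2   # arc spans [phi0, phi0 + ang] around ctr2
  rel <- sweep(centers[, 1:2, drop = FALSE], 2, ctr2[1:2])
  rho <- sqrt(rowSums(rel^2))
  phi <- atan2(rel[, 2], rel[, 1])
  phi_cl <- pmin(pmax(phi, phi0), phi0 + ang)
  on_arc <- abs(phi - phi_cl) < 1e-12
  foot <- cbind(ctr2[1] + radius * cos(phi_cl), ctr2[2] + radius * sin(phi_cl), ctr2[3])
  dist <- sqrt(rowSums((centers - foot)^2))
  s <- (phi_cl - phi0) * radius
  # tangent along increasing phi
  tangent <- cbind(-sin(phi_cl), cos(phi_cl), 0)
  list(dist = dist, s = s, total_len = ang * radius, tangent = tangent,
       on_arc = on_arc)
}

#' Generate a synthetic fiber-bundle DWI phantom
#'
#' Builds the voxel-wise ground-truth tensor field for the requested bundle
#' geometry, simulates the single-tensor diffusion signal
#' `S_k = s0 * exp(-b_k * g_k' D g_k)` for every gradient-table entry, labels
#' the two bundle end-caps as regions 1 and 2, and (optionally) corrupts the
#' signal with Rician noise of per-channel standard deviation `s0 / snr`.
#'
#' @param spec a [bundle_phantom_spec()].
#' @param gradients a [gradient_table()] with at least 7 entries.
#' @return a list with `dwi` ([dwi_volume()]), `truth` (ground-truth
#'   [tensor_field()]), `labels` ([label_volume()]), `bundle_mask`
#'   (logical 3-D array) and `spec`.
#' @export
make_bundle_phantom <- function(spec, gradients = default_gradient_table()) {
  stopifnot(inherits(spec, "bundle_phantom_spec"),
            inherits(gradients, "gradient_table"))
  if (length(gradients$bvals) < 7) {
    stop_validation("at least 7 gradient entries (6 directions + b0) are required")
  }
  shape <- spec$grid_shape
  vs <- spec$voxel_size_mm
  affine <- diag(c(vs, 1))
  v <- prod(shape)
  idx <- as.matrix(expand.grid(x = 0:(shape[1] - 1), y = 0:(shape[2] - 1),
                               z = 0:(shape[3] - 1)))
  centers <- voxel_to_world(idx, affine)

  geo <- bundle_geometry(spec, centers)
  radius_mm <- spec$bundle_radius_vox * min(vs)
  inside <- geo$dist <= radius_mm
  if (!is.null(geo$on_arc)) inside <- inside & geo$on_arc

  d6 <- matrix(0, v, 6)
  d6_out <- oriented_tensor_d6(c(1, 0, 0), spec$outside_eigenvalues)
  d6[] <- matrix(d6_out, v, 6, byrow = TRUE)
  for (i in which(inside)) {
    d6[i, ] <- oriented_tensor_d6(geo$tangent[i, ], spec$inside_eigenvalues)
  }

  cap_mm <- spec$cap_length_vox * min(vs)
  labels <- integer(v)
  labels[inside & geo$s <= cap_mm] <- 1L
  labels[inside & geo$s >= geo$total_len - cap_mm] <- 2L

  if (!is.null(geo$second)) {
    ins2 <- geo$second$dist <= radius_mm & !inside
    for (i in which(ins2)) {
      d6[i, ] <- oriented_tensor_d6(geo$second$tangent[i, ], spec$inside_eigenvalues)
    }
    labels[ins2 & geo$second$s <= cap_mm] <- 3L
    labels[ins2 & geo$second$s >= geo$second$total_len - cap_mm] <- 4L
    inside <- inside | ins2
  }
  if (sum(labels == 1L) == 0 || sum(labels == 2L) == 0) {
    stop_config("bundle end-cap regions are empty: geometry does not fit the grid")
  }

  # forward model, vectorized per gradient
  b <- gradients$bvals
  g <- gradients$bvecs
  k <- length(b)
  sig <- matrix(0, v, k)
  for (j in seq_len(k)) {
    quad <- g[j, 1]^2 * d6[, 1] + g[j, 2]^2 * d6[, 4] + g[j, 3]^2 * d6[, 6] +
      2 * g[j, 1] * g[j, 2] * d6[, 2] +
      2 * g[j, 1] * g[j, 3] * d6[, 3] +
      2 * g[j, 2] * g[j, 3] * d6[, 5]
    sig[, j] <- spec$s0 * exp(-b[j] * quad)
  }
  if (!is.null(spec$snr)) {
    sigma <- spec$s0 / spec$snr
    sig <- with_seed(spec$seed, {
      re <- sig + matrix(rnorm(v * k, sd = sigma), v, k)
      im <- matrix(rnorm(v * k, sd = sigma), v, k)
      sqrt(re^2 + im^2)
    })
  }

  truth <- tensor_field(array(d6, c(shape, 6)), vs, affine)
  list(dwi = dwi_volume(array(sig, c(shape, k)), vs, affine),
       truth = truth,
       labels = label_volume(array(labels, shape), vs, affine,
                             region_names = paste0("cap_", seq_len(max(labels)))),
       bundle_mask = array(inside, shape),
       spec = spec)
}

#' Write a bundle phantom to disk
#'
#' Writes the DWI as 4-D NIfTI-1 plus FSL bval/bvec, the label volume as an
#' integer NIfTI-1, and the ground-truth FA/MD maps.
#'
#' @param phantom result of [make_bundle_phantom()].
#' @param gradients the [gradient_table()] used to simulate it.
#' @param dir output directory.
#' @return invisibly, the output directory.
#' @export
write_bundle_phantom <- function(phantom, gradients, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_nifti(phantom$dwi$data, file.path(dir, "dwi.nii.gz"), phantom$dwi$affine)
  write_gradients(gradients, file.path(dir, "dwi.bval"), file.path(dir, "dwi.bvec"))
  write_nifti(phantom$labels$labels, file.path(dir, "labels.nii.gz"),
              phantom$labels$affine)
  write_nifti(phantom$truth$fa, file.path(dir, "fa_truth.nii.gz"), phantom$truth$affine)
  write_nifti(phantom$truth$md, file.path(dir, "md_truth.nii.gz"), phantom$truth$affine)
  invisible(dir)
}
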