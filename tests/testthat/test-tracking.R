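gt <- default_gradient_table()

test_that("seed selection applies the strict FA > threshold rule", {
  field <- uniform_field(shape = c(5, 5, 5))
  field$fa[] <- 0.8
  expect_equal(nrow(select_seeds(field)), 125)
  field$fa[] <- 0.25
  expect_warning(seeds <- select_seeds(field), "empty")
  expect_equal(nrow(seeds), 0)
  field$fa[] <- 0.3   # exactly at the threshold: excluded
  expect_warning(seeds <- select_seeds(field), "empty")
  expect_equal(nrow(seeds), 0)
  field$fa[] <- 0.3 + 1e-9
  expect_equal(nrow(select_seeds(field)), 125)
  # seeds_per_voxel multiplies the seed count
  field$fa[] <- 0.8
  cfg <- tracking_config(seeds_per_voxel = 3)
  expect_equal(nrow(select_seeds(field, cfg)), 375)
})

test_that("tensor deflection follows v_out = normalize(D v_in)", {
  # uniform D = diag(3,1,1): v_in = (1,1,0)/sqrt(2) deflects to (3,1,0)/sqrt(10)
  field <- uniform_field(shape = c(21, 21, 21), ev = c(3e-3, 1e-3, 1e-3))
  cfg <- tracking_config(step_size_mm = 1, max_angle_deg = 179)
  start <- as.numeric(iscn:::voxel_to_world(matrix(c(10, 10, 10), 1), field$affine))
  ht <- iscn:::half_track(field, start, c(1, 1, 0) / sqrt(2), cfg, 1,
                          iscn:::affine_inverse(field$affine),
                          cos(179 * pi / 180))
  first_dir <- ht$points[2, ] - ht$points[1, ]
  expect_equal(first_dir, c(3, 1, 0) / sqrt(10), tolerance = 1e-12)
  # isotropic tensor: v_out = v_in (straight continuation)
  iso <- uniform_field(shape = c(21, 21, 21), ev = c(1e-3, 1e-3, 1e-3))
  iso$fa[] <- 0.5  # isotropy would otherwise stop tracking immediately
  v0 <- c(1, 2, 2) / 3
  ht2 <- iscn:::half_track(iso, start, v0, cfg, 1,
                           iscn:::affine_inverse(iso$affine), cos(179 * pi / 180))
  dirs <- diff(ht2$points)
  expect_equal(dirs, matrix(rep(v0, nrow(dirs)), ncol = 3, byrow = TRUE),
               tolerance = 1e-12)
})

test_that("uniform anisotropic field tracks straight to the boundary", {
  field <- uniform_field(shape = c(20, 8, 8))
  sl <- propagate(field, c(10, 4, 4), tracking_config(step_size_mm = 1))
  expect_identical(sl$termination_reasons, c("out_of_bounds", "out_of_bounds"))
  # straight along x: y, z constant
  expect_lt(max(abs(sweep(sl$points[, 2:3], 2, sl$points[1, 2:3]))), 1e-9)
  # point spacing is exactly the step size
  spacing <- sqrt(rowSums(diff(sl$points)^2))
  expect_equal(spacing, rep(1, length(spacing)), tolerance = 1e-9)
  # every point maps into the grid
  vox <- iscn:::world_to_voxel_index(sl$points, field$affine)
  expect_true(all(iscn:::in_grid(vox, field$grid_shape)))
})

test_that("stop rule is strict: FA exactly at the stop threshold continues", {
  field <- uniform_field(shape = c(20, 8, 8))
  field$fa[] <- 0.2        # exactly the stop threshold everywhere
  sl <- propagate(field, c(10, 4, 4), tracking_config(step_size_mm = 1))
  expect_identical(sl$termination_reasons, c("out_of_bounds", "out_of_bounds"))
  field$fa[] <- 0.2 - 1e-9
  sl2 <- propagate(field, c(10, 4, 4), tracking_config(step_size_mm = 1))
  expect_identical(sl2$termination_reasons, c("low_fa", "low_fa"))
  expect_equal(nrow(sl2$points), 1)
})

test_that("straight-bundle phantom connects its end caps", {
  ph <- make_bundle_phantom(bundle_phantom_spec(), gt)
  field <- fit_tensor(ph$dwi, gt)
  tract <- track_whole_volume(field)
  expect_equal(length(tract$streamlines), nrow(select_seeds(field)))
  ep <- assign_endpoints(tract, ph$labels)
  hit <- mean(ep[, 1] == 1 & ep[, 2] == 2)
  expect_gte(hit, 0.95)
})

test_that("sharp-bend phantom terminates every bend-crossing streamline by curvature", {
  ph <- make_bundle_phantom(bundle_phantom_spec(grid_shape = c(30, 30, 14),
                                                geometry = "sharp_bend"), gt)
  field <- fit_tensor(ph$dwi, gt)
  tract <- track_whole_volume(field)
  ang <- ph$spec$arc_angle_deg * pi / 180
  u1 <- c(1, 0, 0)
  u2 <- c(cos(ang), sin(ang), 0)
  arms <- t(vapply(tract$streamlines, function(s) {
    vox <- iscn:::world_to_voxel_index(s$points, field$affine)
    vox <- vox[iscn:::in_grid(vox, field$grid_shape), , drop = FALSE] + 1L
    e1 <- cbind(ph$truth$e1[cbind(vox, 1L)], ph$truth$e1[cbind(vox, 2L)],
                ph$truth$e1[cbind(vox, 3L)])
    inb <- ph$bundle_mask[vox]
    c(any(inb & abs(e1 %*% u1) > 0.99), any(inb & abs(e1 %*% u2) > 0.99))
  }, logical(2)))
  crossing <- arms[, 1] & arms[, 2]
  expect_gt(sum(crossing), 100)
  curv <- vapply(tract$streamlines, function(s)
    any(s$termination_reasons == "curvature"), logical(1))
  expect_equal(mean(curv[crossing]), 1)
})

test_that("arc phantom tracks through its smooth turn without curvature stops", {
  ph <- make_bundle_phantom(bundle_phantom_spec(grid_shape = c(30, 30, 14),
                                                geometry = "arc"), gt)
  field <- fit_tensor(ph$dwi, gt)
  tract <- track_whole_volume(field)
  reasons <- termination_summary(tract)
  expect_equal(unname(reasons["curvature"]), 0L)
  ep <- assign_endpoints(tract, ph$labels)
  expect_gt(mean(ep[, 1] == 1 & ep[, 2] == 2), 0.5)
})

test_that("tracking is deterministic and curvature-bounded within half-tracks", {
  ph <- make_bundle_phantom(bundle_phantom_spec(grid_shape = c(30, 30, 14),
                                                geometry = "sharp_bend"), gt)
  field <- fit_tensor(ph$dwi, gt)
  t1 <- track_whole_volume(field)
  t2 <- track_whole_volume(field)
  expect_identical(t1, t2)
  cfg <- tracking_config()
  cos_lim <- cos(cfg$max_angle_deg * pi / 180) - 1e-9
  for (s in t1$streamlines[seq(1, length(t1$streamlines), by = 7)]) {
    if (nrow(s$points) < 3) next
    dirs <- diff(s$points)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    cosines <- rowSums(dirs[-nrow(dirs), , drop = FALSE] *
                       dirs[-1, , drop = FALSE])
    # the junction between the two half-tracks is exempt from the turn limit
    junction <- s$junction_index - 1L
    ok <- cosines >= cos_lim
    ok[junction] <- TRUE
    expect_true(all(ok))
  }
})

test_that("reflecting the tensor field through a plane reflects the streamlines", {
  ph <- make_bundle_phantom(bundle_phantom_spec(grid_shape = c(24, 24, 10),
                                                geometry = "arc"), gt)
  field <- fit_tensor(ph$dwi, gt)
  # mirror in y: flip voxel order along y and flip the xy/yz tensor components
  ny <- field$grid_shape[2]
  m <- field
  m$d6 <- field$d6[, ny:1, , , drop = FALSE]
  m$d6[, , , 2] <- -m$d6[, , , 2]
  m$d6[, , , 5] <- -m$d6[, , , 5]
  mirrored <- tensor_field(m$d6, field$voxel_size_mm, field$affine)
  t1 <- track_whole_volume(field)
  t2 <- track_whole_volume(mirrored)
  expect_equal(length(t1$streamlines), length(t2$streamlines))
  # match streamlines by mirrored seed voxel and compare reflected points
  seed_key <- function(tr) vapply(tr$streamlines, function(s)
    paste(s$seed_voxel, collapse = ","), "")
  k1 <- seed_key(t1)
  mirror_seed <- vapply(t1$streamlines, function(s)
    paste(c(s$seed_voxel[1], ny - 1L - s$seed_voxel[2], s$seed_voxel[3]),
          collapse = ","), "")
  idx <- match(mirror_seed, seed_key(t2))
  expect_false(anyNA(idx))
  y_extent <- (ny - 1) * field$voxel_size_mm[2]
  for (s in seq(1, length(k1), by = 11)) {
    p1 <- t1$streamlines[[s]]$points
    p2 <- t2$streamlines[[idx[s]]]$points
    p1_mirrored <- cbind(p1[, 1], y_extent - p1[, 2], p1[, 3])
    expect_equal(p2, p1_mirrored, tolerance = 1e-8)
  }
})
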