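gt <- default_gradient_table()

# shared fixture: a small labeled grid and a hand-built tractogram
grid_shape <- c(8, 8, 8)
affine <- diag(c(2, 2, 2, 1))
labs <- array(0L, grid_shape)
labs[1:2, , ] <- 1L
labs[7:8, , ] <- 2L
labs[4, 8, ] <- 3L
labels <- label_volume(labs, c(2, 2, 2), affine)

test_that("endpoint assignment maps terminal points to containing voxels", {
  from <- rbind(c(0, 3, 3), c(1, 2, 2), c(3, 3, 3), c(0, 0, 0))
  to <- rbind(c(7, 3, 3), c(6, 2, 2), c(4, 4, 4), c(1, 1, 1))
  tract <- toy_tractogram(from, to, affine, grid_shape)
  ep <- assign_endpoints(tract, labels)
  expect_equal(ep[1, ], c(region_i = 1L, region_j = 2L))
  expect_equal(ep[2, ], c(region_i = 1L, region_j = 2L))
  expect_equal(ep[3, ], c(region_i = 0L, region_j = 0L))   # background ends
  expect_equal(ep[4, ], c(region_i = 1L, region_j = 1L))   # same region
  # grid mismatch is rejected
  other <- label_volume(labs, c(1, 1, 1), diag(4))
  expect_error(assign_endpoints(tract, other), "grid")
})

test_that("network counts match a brute-force per-streamline tally", {
  set.seed(42)
  n <- 20
  from_x <- sample(0:1, n, replace = TRUE)
  to_x <- sample(6:7, n, replace = TRUE)
  from <- cbind(from_x, sample(0:7, n, TRUE), sample(0:7, n, TRUE))
  to <- cbind(to_x, sample(0:7, n, TRUE), sample(0:7, n, TRUE))
  # send a few to background or region 3 for variety
  to[1:3, ] <- matrix(rep(c(3, 3, 3), 3), 3, byrow = TRUE)
  to[4:5, ] <- matrix(rep(c(3, 7, 0), 2), 2, byrow = TRUE)
  tract <- toy_tractogram(from, to, affine, grid_shape)
  field <- uniform_field(grid_shape, voxel = c(2, 2, 2))
  net <- build_network(tract, labels, field, m = 1)
  ep <- assign_endpoints(tract, labels)
  expect_equal(net$counts, oracle_tally(ep, 3))
  expect_equal(net$n_all, n)
  # conservation: upper-triangle counts never exceed the streamline total
  expect_lte(sum(net$counts[upper.tri(net$counts)]), net$n_all)
})

test_that("edge FA/MD average over the deduplicated union of visited voxels", {
  field <- uniform_field(grid_shape, voxel = c(2, 2, 2))
  field$fa[] <- 0
  field$md[] <- 0
  # streamline 1 visits voxels (1,3,3) and (2,3,3); streamline 2 revisits
  # (2,3,3) many times -- deduplication means each voxel counts once
  field$fa[2, 4, 4] <- 0.4; field$md[2, 4, 4] <- 1e-3
  field$fa[3, 4, 4] <- 0.6; field$md[3, 4, 4] <- 3e-3
  p1 <- iscn:::voxel_to_world(rbind(c(1, 3, 3), c(2, 3, 3)), affine)
  p2 <- iscn:::voxel_to_world(rbind(c(2, 3, 3), c(2, 3, 3), c(2, 3, 3),
                                    c(1, 3, 3)), affine)
  # both run from region-1 territory to region-2 territory via those voxels
  ends <- iscn:::voxel_to_world(rbind(c(0, 3, 3), c(7, 3, 3)), affine)
  mk <- function(mid) list(points = rbind(ends[1, , drop = FALSE], mid,
                                          ends[2, , drop = FALSE]),
                           seed_voxel = c(0L, 3L, 3L),
                           termination_reasons = c("low_fa", "low_fa"))
  tract <- tractogram(list(mk(p1), mk(p2)), affine, grid_shape)
  net <- build_network(tract, labels, field, m = 1)
  visited <- unique(rbind(c(1, 3, 3), c(2, 3, 3), c(0, 3, 3), c(7, 3, 3)))
  expected_fa <- mean(field$fa[visited + 1])
  expect_equal(net$fa[1, 2], expected_fa)
  expect_equal(net$fa[1, 2], mean(c(0.4, 0.6, 0, 0)))
})

test_that("connection threshold m zeroes attributes monotonically", {
  # spiked tractogram: edges with 6, 4 and 2 streamlines
  reps <- c(6, 4, 2)
  from <- do.call(rbind, list(
    matrix(rep(c(0, 1, 1), reps[1]), ncol = 3, byrow = TRUE),
    matrix(rep(c(0, 5, 5), reps[2]), ncol = 3, byrow = TRUE),
    matrix(rep(c(3, 7, 0), reps[3]), ncol = 3, byrow = TRUE)))
  to <- do.call(rbind, list(
    matrix(rep(c(7, 1, 1), reps[1]), ncol = 3, byrow = TRUE),
    matrix(rep(c(3, 7, 1), reps[2]), ncol = 3, byrow = TRUE),
    matrix(rep(c(7, 0, 0), reps[3]), ncol = 3, byrow = TRUE)))
  tract <- toy_tractogram(from, to, affine, grid_shape)
  field <- uniform_field(grid_shape, voxel = c(2, 2, 2))
  nets <- lapply(c(1, 3, 5), function(m) build_network(tract, labels, field, m = m))
  edges_present <- function(net) which(net$density > 0 & upper.tri(net$density))
  e1 <- edges_present(nets[[1]])
  e3 <- edges_present(nets[[2]])
  e5 <- edges_present(nets[[3]])
  expect_length(e1, 3)
  expect_length(e3, 2)
  expect_length(e5, 1)
  expect_true(all(e5 %in% e3) && all(e3 %in% e1))
  # surviving edges keep identical attribute values as m rises
  expect_equal(nets[[2]]$density[e3], nets[[1]]$density[e3])
  expect_equal(nets[[3]]$fa[e5], nets[[1]]$fa[e5])
  expect_equal(nets[[3]]$md[e5], nets[[1]]$md[e5])
  # raw counts are never altered by m
  expect_equal(nets[[1]]$counts, nets[[3]]$counts)
})

test_that("straight phantom yields the single ground-truth connection", {
  ph <- make_bundle_phantom(bundle_phantom_spec(), gt)
  field <- fit_tensor(ph$dwi, gt)
  tract <- track_whole_volume(field)
  net <- build_network(tract, ph$labels, field, m = 1)
  ut <- upper.tri(net$density)
  expect_equal(sum(net$density[ut] > 0), 1)
  expect_equal(net$density[1, 2], net$counts[1, 2] / net$n_all)
  expect_lte(sum(net$density[ut]), 1)
  expect_gt(net$fa[1, 2], 0.3)
})

test_that("group averaging and the never-connected mask follow the definitions", {
  mk <- function(cd12) {
    counts <- matrix(0L, 3, 3); counts[1, 2] <- counts[2, 1] <- 10L
    net <- connectivity_network(counts, 100, m = 1)
    net$density[1, 2] <- net$density[2, 1] <- cd12
    net
  }
  single <- group_average(list(mk(0.2)))
  expect_equal(single$density[1, 2], 0.2)
  avg <- group_average(list(mk(0.2), mk(0.4)))
  expect_equal(avg$density[1, 2], 0.3)
  expect_false(avg$never_connected[1, 2])
  expect_true(avg$never_connected[1, 3])
  expect_true(avg$never_connected[2, 3])
  bad <- connectivity_network(matrix(0L, 4, 4), 10, m = 1)
  expect_error(group_average(list(mk(0.2), bad)), "mixed")
})

test_that("empty tractograms produce a flagged degenerate network", {
  tract <- tractogram(list(), affine, grid_shape)
  field <- uniform_field(grid_shape, voxel = c(2, 2, 2))
  expect_warning(net <- build_network(tract, labels, field), "degenerate")
  expect_true(net$degenerate)
  expect_equal(net$n_all, 0L)
  expect_true(all(net$density == 0))
})
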