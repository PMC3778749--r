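#' Individual structural connectivity network (ISCN)
#'
#' A per-subject network over R atlas regions. Edges carry four attributes:
#' raw streamline counts `n_ij`, fiber density `cd_ij = n_ij / n_all` (where
#' `n_all` is the subject's total streamline count), mean FA and mean MD over
#' the voxels traversed by the edge's streamlines. Edges with fewer than `m`
#' streamlines are not considered connections and carry exact 0 in density,
#' FA and MD (raw counts are kept), which yields fixed-length, comparable
#' feature vectors across subjects.
#'
#' @param counts symmetric non-negative integer R x R matrix of streamline
#'   counts with zero diagonal.
#' @param n_all total number of streamlines for the subject (>= sum of counts).
#' @param fa,md symmetric R x R matrices of mean FA / mean MD per edge.
#' @param m connection threshold: minimum streamline count for a region pair
#'   to count as connected (1, 3 and 5 in typical use).
#' @param region_names optional character vector of region names.
#' @return an object of class `connectivity_network`.
#' @export
connectivity_network <- function(counts, n_all, fa = NULL, md = NULL, m = 1,
                                 region_names = NULL) {
  counts <- as.matrix(counts)
  r <- nrow(counts)
  if (ncol(counts) != r) stop_validation("counts must be square")
  if (any(counts < 0)) stop_validation("counts must be non-negative")
  if (any(diag(counts) != 0)) stop_validation("counts diagonal must be zero")
  if (!isTRUE(all.equal(counts, t(counts)))) stop_validation("counts must be symmetric")
  if (m < 1 || m != round(m)) stop_validation("m must be a positive integer")
  if (n_all < 0) stop_validation("n_all must be non-negative")
  zero <- matrix(0, r, r)
  if (is.null(fa)) fa <- zero
  if (is.null(md)) md <- zero
  if (any(fa < -1e-12) || any(fa > 1 + 1e-12)) stop_validation("FA entries must lie in [0, 1]")
  connected <- counts >= m
  density <- if (n_all > 0) counts / n_all else zero
  density[!connected] <- 0
  fa <- as.matrix(fa); md <- as.matrix(md)
  fa[!connected] <- 0
  md[!connected] <- 0
  diag(density) <- diag(fa) <- diag(md) <- 0
  if (is.null(region_names)) region_names <- paste0("region_", seq_len(r))
  structure(list(n_regions = r, counts = counts, density = density,
                 fa = fa, md = md, n_all = as.integer(n_all), m = as.integer(m),
                 region_names = region_names,
                 degenerate = n_all == 0),
            class = "connectivity_network")
}

#' @export
print.connectivity_network <- function(x, ...) {
  n_edges <- sum(x$density[upper.tri(x$density)] > 0)
  cat(sprintf("connectivity_network: %d regions, %d connections (m = %d), n_all = %d\n",
              x$n_regions, n_edges, x$m, x$n_all))
  invisible(x)
}

#' Map streamline endpoints to atlas regions
#'
#' Each streamline's two terminal points are assigned the label of their
#' containing voxel (floor-based lookup on the label volume's grid; 0 =
#' background / outside grid). Streamlines with either endpoint in background
#' or with both endpoints in the same region contribute no inter-regional
#' pair.
#'
#' @param tract a [tractogram()].
#' @param labels a [label_volume()] sharing the tractogram's reference grid.
#' @return integer matrix with one row per streamline and columns
#'   `region_i`, `region_j` (`region_i <= region_j`; 0 where unassigned).
#' @export
assign_endpoints <- function(tract, labels) {
  stopifnot(inherits(tract, "tractogram"), inherits(labels, "label_volume"))
  if (!isTRUE(all.equal(tract$affine, labels$affine, tolerance = 1e-8)) ||
      !all(tract$grid_shape == dim(labels$labels))) {
    stop_validation("tractogram and label volume must share the reference grid")
  }
  n <- length(tract$streamlines)
  out <- matrix(0L, n, 2, dimnames = list(NULL, c("region_i", "region_j")))
  if (n == 0) return(out)
  ends <- do.call(rbind, lapply(tract$streamlines, function(s) {
    p <- s$points
    rbind(p[1, ], p[nrow(p), ])
  }))
  vox <- world_to_voxel_index(ends, labels$affine)
  ok <- in_grid(vox, dim(labels$labels))
  lab <- integer(nrow(vox))
  lab[ok] <- labels$labels[vox[ok, , drop = FALSE] + 1L]
  a <- lab[seq(1, 2 * n, by = 2)]
  b <- lab[seq(2, 2 * n, by = 2)]
  out[, 1] <- pmin(a, b)
  out[, 2] <- pmax(a, b)
  out
}

# unique linear voxel indices (1-based) visited by a streamline's points
streamline_voxels <- function(points, affine, grid_shape) {
  vox <- world_to_voxel_index(points, affine)
  keep <- in_grid(vox, grid_shape)
  vox <- vox[keep, , drop = FALSE]
  if (nrow(vox) == 0) return(integer(0))
  lin <- 1L + vox[, 1] + grid_shape[1] * (vox[, 2] + grid_shape[2] * vox[, 3])
  unique(lin)
}

#' Build an ISCN from a tractogram, label volume and tensor field
#'
#' Counts streamlines per region pair (endpoints via [assign_endpoints()]),
#' sets `n_all` to the total number of streamlines launched, and computes each
#' connected edge's mean FA and mean MD over the deduplicated union of voxels
#' visited by that edge's streamlines (each voxel counted once). Edges with
#' fewer than `m` streamlines carry 0 in all attributes.
#'
#' @param tract a [tractogram()].
#' @param labels a [label_volume()] on the same grid.
#' @param field the [tensor_field()] supplying FA/MD maps.
#' @param m connection threshold (minimum streamline count), default 1.
#' @return a [connectivity_network()]; degenerate (all-zero, flagged) if the
#'   tractogram is empty.
#' @export
build_network <- function(tract, labels, field, m = 1) {
  stopifnot(inherits(field, "tensor_field"))
  r <- length(labels$region_names)
  pairs <- assign_endpoints(tract, labels)
  n_all <- length(tract$streamlines)
  counts <- matrix(0L, r, r)
  fa <- matrix(0, r, r)
  md <- matrix(0, r, r)
  valid <- pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2]
  if (any(valid)) {
    key <- paste(pairs[valid, 1], pairs[valid, 2])
    tab <- table(key)
    ij <- do.call(rbind, strsplit(names(tab), " "))
    ij <- matrix(as.integer(ij), ncol = 2)
    for (e in seq_len(nrow(ij))) {
      i <- ij[e, 1]; j <- ij[e, 2]
      counts[i, j] <- counts[j, i] <- as.integer(tab[e])
    }
    # mean FA/MD over the union of voxels visited by each edge's streamlines
    which_valid <- which(valid)
    edge_of <- match(key, names(tab))
    vox_sets <- vector("list", nrow(ij))
    for (s in seq_along(which_valid)) {
      sl <- tract$streamlines[[which_valid[s]]]
      vx <- streamline_voxels(sl$points, field$affine, field$grid_shape)
      e <- edge_of[s]
      vox_sets[[e]] <- c(vox_sets[[e]], vx)
    }
    for (e in seq_len(nrow(ij))) {
      vx <- unique(vox_sets[[e]])
      i <- ij[e, 1]; j <- ij[e, 2]
      fa[i, j] <- fa[j, i] <- mean(field$fa[vx])
      md[i, j] <- md[j, i] <- mean(field$md[vx])
    }
  }
  net <- connectivity_network(counts, n_all, fa, md, m = m,
                              region_names = labels$region_names)
  if (n_all == 0) warning("empty tractogram: degenerate all-zero network")
  net
}

#' Group-average connectivity matrices
#'
#' Entrywise mean of each attribute across subjects, plus a mask of edges
#' with no connection in any subject of the group (the "never connected"
#' entries shown black in group-average connectivity figures).
#'
#' @param networks list of [connectivity_network()] objects with identical
#'   region sets.
#' @return list with `density`, `fa`, `md` (mean matrices), `counts` (mean raw
#'   counts) and `never_connected` (logical matrix).
#' @export
group_average <- function(networks) {
  if (length(networks) == 0) stop_validation("no networks supplied")
  r <- networks[[1]]$n_regions
  if (!all(vapply(networks, function(n) n$n_regions, 0L) == r)) {
    stop_validation("networks have mixed region counts")
  }
  avg <- function(attr) Reduce(`+`, lapply(networks, `[[`, attr)) / length(networks)
  any_conn <- Reduce(`|`, lapply(networks, function(n) n$density > 0))
  list(density = avg("density"), fa = avg("fa"), md = avg("md"),
       counts = avg("counts"), never_connected = !any_conn)
}

#' Write an ISCN as CSV edge list, dense matrices and JSON metadata
#'
#' @param network a [connectivity_network()].
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_network <- function(network, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  idx <- edge_index_pairs(network$n_regions)
  el <- data.frame(region_i = idx[, 1], region_j = idx[, 2],
                   count = network$counts[idx],
                   cd = network$density[idx],
                   fa = network$fa[idx],
                   md = network$md[idx])
  write.csv(el, file.path(dir, "edges.csv"), row.names = FALSE)
  for (attr in c("density", "fa", "md")) {
    write.table(network[[attr]], file.path(dir, paste0(attr, ".csv")),
                sep = ",", row.names = FALSE, col.names = FALSE)
  }
  writeLines(network$region_names, file.path(dir, "regions.tsv"))
  jsonlite::write_json(list(n_all = network$n_all, m = network$m,
                            n_regions = network$n_regions),
                       file.path(dir, "network.json"), auto_unbox = TRUE)
  invisible(dir)
}
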