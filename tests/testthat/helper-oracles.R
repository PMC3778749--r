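# Independent oracles and small fixture builders used across the test suite.
# These deliberately re-derive quantities by the most naive route available
# (direct counting, exhaustive enumeration, closed forms) so they share no
# code with the implementation they check.

# --- information gain oracle -------------------------------------------------

oracle_entropy <- function(labels) {
  counts <- as.numeric(table(labels))
  counts <- counts[counts > 0]
  p <- counts / sum(counts)
  -sum(p * log2(p))
}

# Exhaustive best-cut search: every midpoint between adjacent distinct values
# is evaluated by literally partitioning the vectors.
oracle_best_cut <- function(x, y) {
  ux <- sort(unique(x))
  cuts <- (ux[-1] + ux[-length(ux)]) / 2
  best <- NULL
  for (cut in cuts) {
    yl <- y[x <= cut]
    yr <- y[x > cut]
    h <- (length(yl) * oracle_entropy(yl) + length(yr) * oracle_entropy(yr)) / length(y)
    if (is.null(best) || h < best$h - 1e-12) best <- list(cut = cut, h = h)
  }
  best
}

oracle_mdl_ok <- function(x, y, cut) {
  yl <- y[x <= cut]
  yr <- y[x > cut]
  n <- length(y)
  h <- oracle_entropy(y)
  hl <- oracle_entropy(yl)
  hr <- oracle_entropy(yr)
  gain <- h - (length(yl) * hl + length(yr) * hr) / n
  k <- length(unique(y))
  k1 <- length(unique(yl))
  k2 <- length(unique(yr))
  delta <- log2(3^k - 2) - (k * h - k1 * hl - k2 * hr)
  gain > (log2(n - 1) + delta) / n
}

oracle_partition <- function(x, y, force) {
  if (length(unique(x)) < 2 || length(unique(y)) < 2) return(numeric(0))
  best <- oracle_best_cut(x, y)
  if (!force && !oracle_mdl_ok(x, y, best$cut)) return(numeric(0))
  l <- x <= best$cut
  c(oracle_partition(x[l], y[l], FALSE), best$cut,
    oracle_partition(x[!l], y[!l], FALSE))
}

oracle_information_gain <- function(x, y) {
  y <- as.factor(y)
  if (length(unique(y)) < 2 || length(unique(x)) < 2) return(0)
  cuts <- oracle_partition(x, y, force = length(unique(x)) == 2)
  if (length(cuts) == 0) return(0)
  bin <- findInterval(x, sort(cuts))
  h_cond <- 0
  for (b in unique(bin)) {
    h_cond <- h_cond + sum(bin == b) / length(y) * oracle_entropy(y[bin == b])
  }
  oracle_entropy(y) - h_cond
}

# --- connectivity tally oracle ----------------------------------------------

# per-streamline tally of endpoint pairs into a counts matrix, by loop
oracle_tally <- function(pairs, n_regions) {
  counts <- matrix(0L, n_regions, n_regions)
  for (s in seq_len(nrow(pairs))) {
    i <- pairs[s, 1]; j <- pairs[s, 2]
    if (i > 0 && j > 0 && i != j) {
      counts[i, j] <- counts[i, j] + 1L
      counts[j, i] <- counts[j, i] + 1L
    }
  }
  counts
}

# --- fixture builders --------------------------------------------------------

# uniform tensor field: every voxel carries the tensor with eigenvalues `ev`
# and principal axis `axis`
uniform_field <- function(shape = c(10, 10, 10), ev = c(1.7e-3, 3e-4, 3e-4),
                          axis = c(1, 0, 0), voxel = c(2, 2, 2)) {
  d6_row <- iscn:::oriented_tensor_d6(axis, ev)
  d6 <- array(rep(d6_row, each = prod(shape)), c(shape, 6))
  tensor_field(d6, voxel)
}

# hand-built tractogram: one streamline per row of `from`/`to` voxel indices
# (0-based), as straight two-point segments between the voxel centers
toy_tractogram <- function(from, to, affine, grid_shape) {
  streamlines <- lapply(seq_len(nrow(from)), function(s) {
    p <- rbind(iscn:::voxel_to_world(from[s, , drop = FALSE], affine),
               iscn:::voxel_to_world(to[s, , drop = FALSE], affine))
    list(points = p, seed_voxel = as.integer(from[s, ]),
         termination_reasons = c("low_fa", "low_fa"))
  })
  tractogram(streamlines, affine, grid_shape)
}

# well-separated two-class pattern blobs (classes differ in direction, not
# just level, so correlation-based similarity also separates them)
make_blobs <- function(n_per_class = 15, p = 12, sep = 6, sd = 0.5, seed = 99) {
  stopifnot(p %% 2 == 0)
  mu_a <- rep(c(sep, 0), p / 2)
  mu_b <- rep(c(0, sep), p / 2)
  iscn:::with_seed(seed, {
    x <- rbind(
      matrix(rnorm(n_per_class * p, mean = rep(mu_a, each = n_per_class), sd = sd),
             n_per_class, p),
      matrix(rnorm(n_per_class * p, mean = rep(mu_b, each = n_per_class), sd = sd),
             n_per_class, p))
    list(x = x, y = factor(rep(c("a", "b"), each = n_per_class)))
  })
}
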