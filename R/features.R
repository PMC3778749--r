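#' Vectorize cohort networks into an edge-feature matrix
#'
#' One attribute (`cd`, `fa` or `md`) of every subject's network is unrolled
#' into the R(R-1)/2 upper-triangle edges, in lexicographic (region_i,
#' region_j) order with region_i < region_j. Absent edges are exact 0 (see
#' [connectivity_network()]), so all subjects share a fixed-length feature
#' vector.
#'
#' @param cohort a `cohort_dataset`.
#' @param attribute one of `"cd"`, `"fa"`, `"md"`.
#' @return an object of class `feature_matrix`: list with `values`
#'   (n_subjects x n_features), `feature_index` (edge pairs), `labels`
#'   (factor), `attribute`.
#' @export
vectorize <- function(cohort, attribute = c("cd", "fa", "md")) {
  attribute <- match.arg(attribute)
  stopifnot(inherits(cohort, "cohort_dataset"))
  r <- cohort$n_regions
  if (!all(vapply(cohort$networks, function(n) n$n_regions, 0L) == r)) {
    stop_validation("networks have mixed region counts")
  }
  idx <- edge_index_pairs(r)
  slot <- if (attribute == "cd") "density" else attribute
  values <- do.call(rbind, lapply(cohort$networks, function(n) n[[slot]][idx]))
  structure(list(values = values, feature_index = idx,
                 labels = cohort$labels, attribute = attribute),
            class = "feature_matrix")
}

#' Fold an edge-feature vector back into a symmetric matrix
#'
#' Inverse of the [vectorize()] edge ordering.
#'
#' @param x numeric vector of length R(R-1)/2.
#' @param n_regions R.
#' @return symmetric R x R matrix with zero diagonal.
#' @export
devectorize <- function(x, n_regions) {
  idx <- edge_index_pairs(n_regions)
  if (length(x) != nrow(idx)) stop_validation("length(x) must equal R(R-1)/2")
  m <- matrix(0, n_regions, n_regions)
  m[idx] <- x
  m + t(m)
}

# Shannon entropy of a label vector, in bits
entropy_bits <- function(y) {
  p <- table(y)
  p <- p[p > 0] / length(y)
  -sum(p * log2(p))
}

# Fayyad-Irani MDL acceptance test for one binary split
mdl_accepts <- function(y, left) {
  n <- length(y)
  h <- entropy_bits(y)
  h1 <- entropy_bits(y[left])
  h2 <- entropy_bits(y[!left])
  w <- mean(left)
  gain <- h - (w * h1 + (1 - w) * h2)
  k <- length(unique(y))
  k1 <- length(unique(y[left]))
  k2 <- length(unique(y[!left]))
  delta <- log2(3^k - 2) - (k * h - k1 * h1 - k2 * h2)
  gain > (log2(n - 1) + delta) / n
}

# recursive entropy-minimizing cut search with MDL stopping; returns cut values
find_cuts <- function(x, y, force_first) {
  n <- length(x)
  ux <- sort(unique(x))
  if (length(ux) < 2 || length(unique(y)) < 2) return(numeric(0))
  candidates <- (ux[-1] + ux[-length(ux)]) / 2
  best_cut <- NA_real_
  best_h <- Inf
  for (cut in candidates) {
    left <- x <= cut
    w <- mean(left)
    h <- w * entropy_bits(y[left]) + (1 - w) * entropy_bits(y[!left])
    if (h < best_h - 1e-12) {
      best_h <- h
      best_cut <- cut
    }
  }
  left <- x <= best_cut
  if (!force_first && !mdl_accepts(y, left)) return(numeric(0))
  c(find_cuts(x[left], y[left], FALSE),
    best_cut,
    find_cuts(x[!left], y[!left], FALSE))
}

#' Information gain of a continuous feature for a class split
#'
#' `IG = H(labels) - sum_bins (|bin|/n) H(labels in bin)`, in bits, where the
#' bins come from supervised discretization of the feature on the same data:
#' recursive entropy-minimizing binary splits with the Fayyad-Irani MDL
#' stopping criterion. A feature with exactly two distinct values has an
#' unambiguous discretization, so its single possible cut is accepted without
#' the MDL test; for richer features the MDL test governs every split,
#' including the first, and a feature yielding no accepted cut scores 0.
#' Because only the ordering of values enters, IG is invariant to strictly
#' monotone transforms of the feature.
#'
#' @param feature_column numeric vector.
#' @param labels class labels (two classes expected).
#' @return non-negative information gain in bits.
#' @export
information_gain <- function(feature_column, labels) {
  if (length(feature_column) != length(labels) || length(labels) < 2) {
    stop_validation("feature and labels must have equal length >= 2")
  }
  y <- as.factor(labels)
  if (length(unique(y)) < 2) {
    warning("single class present: information gain defined as 0")
    return(0)
  }
  x <- as.numeric(feature_column)
  n_distinct <- length(unique(x))
  if (n_distinct < 2) return(0)
  cuts <- find_cuts(x, y, force_first = n_distinct == 2)
  if (length(cuts) == 0) return(0)
  bins <- findInterval(x, sort(cuts))
  h_cond <- 0
  for (b in unique(bins)) {
    sel <- bins == b
    h_cond <- h_cond + mean(sel) * entropy_bits(y[sel])
  }
  max(0, entropy_bits(y) - h_cond)
}

#' Rank and select features by information gain on training data
#'
#' Features are ranked by information gain (descending, ties broken by
#' lexicographic feature index). With `top_n = "all_positive"` (default) every
#' feature with positive gain is kept; an integer keeps the `top_n` best
#' (capped at the feature count). An empty selection (all gains zero) is
#' returned as such; the cross-validation harness falls back to all features
#' in that degenerate case.
#'
#' @param train a `feature_matrix` built from training subjects only.
#' @param top_n `"all_positive"` or a positive integer.
#' @return list with `selected` (ordered feature column indices), `gains`
#'   (per-feature information gain, in feature order).
#' @export
select_features <- function(train, top_n = "all_positive") {
  stopifnot(inherits(train, "feature_matrix"))
  gains <- apply(train$values, 2, information_gain, labels = train$labels)
  ord <- order(-gains, seq_along(gains))
  if (identical(top_n, "all_positive")) {
    selected <- ord[gains[ord] > 0]
  } else {
    if (!is.numeric(top_n) || top_n < 1) stop_validation("top_n must be a positive integer or 'all_positive'")
    selected <- head(ord, min(as.integer(top_n), length(gains)))
  }
  list(selected = selected, gains = gains)
}

#' Aggregate feature selection across validation rounds
#'
#' Counts, per edge feature, the number of rounds in which it was selected;
#' the highlighted set contains edges selected in strictly more than
#' `round_threshold` rounds (the "more than five rounds" rule used to flag
#' discriminative connections).
#'
#' @param selections list over rounds of selected feature-index vectors.
#' @param n_features total feature count.
#' @param feature_index edge-pair matrix as in [vectorize()].
#' @param round_threshold strict threshold on the round count, default 5.
#' @return an object of class `selection_report`: list with `counts`
#'   (per-feature rounds selected), `highlighted` (feature indices),
#'   `highlighted_edges` (region pairs), `n_rounds`, `round_threshold`.
#' @export
aggregate_selection <- function(selections, n_features, feature_index = NULL,
                                round_threshold = 5) {
  counts <- integer(n_features)
  for (sel in selections) {
    counts[sel] <- counts[sel] + 1L
  }
  highlighted <- which(counts > round_threshold)
  structure(list(counts = counts,
                 highlighted = highlighted,
                 highlighted_edges = if (!is.null(feature_index))
                   feature_index[highlighted, , drop = FALSE] else NULL,
                 per_round = selections,
                 n_rounds = length(selections),
                 round_threshold = round_threshold),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("selection_report: %d rounds, %d features highlighted (> %d rounds)\n",
              x$n_rounds, length(x$highlighted), x$round_threshold))
  invisible(x)
}
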