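#' Specification of a synthetic two-group network cohort
#'
#' Describes cohorts of symmetric weighted connectivity matrices with a
#' planted group difference: a common edge support is drawn once per cohort,
#' per-subject attribute values are drawn around per-attribute baselines, and
#' `affected_edges` randomly chosen present edges receive a standardized mean
#' shift of `effect_size_d` standard deviations in group 2. This emulates the
#' statistical structure that the classification protocol operates on, with
#' known ground truth for recovery testing.
#'
#' @param n_regions number of atlas regions R (features are the R(R-1)/2
#'   upper-triangle edges).
#' @param n_per_group integer pair: subjects in group 1 and group 2.
#' @param baseline_edge_probability probability in (0, 1] that an edge is
#'   present in the cohort's common support.
#' @param attribute_means named baseline means for `cd`, `fa`, `md`.
#' @param attribute_sds named between-subject standard deviations.
#' @param affected_edges number of planted (shifted) edges.
#' @param effect_size_d standardized mean shift applied to affected edges in
#'   group 2 (0 = null cohort).
#' @param affected_attributes which attributes carry the shift.
#' @param n_all nominal total streamline count per subject, used to derive
#'   integer edge counts from densities.
#' @param edge_mean_cv coefficient of variation of the per-edge baseline
#'   means, drawn once per cohort and shared by all subjects. Real
#'   connectivity matrices are strongly heterogeneous across edges (fiber
#'   density spans orders of magnitude; FA and MD differ by tract), so the
#'   default is substantial (0.35). Fiber-density baselines are log-normal;
#'   FA and MD baselines are normal (FA clipped away from the 0/1 bounds).
#' @param edge_sd_jitter half-width of the uniform factor on the per-edge
#'   within-group standard deviation: edge e uses
#'   `sd_e = attribute_sd * U(1 - jitter, 1 + jitter)`. The planted group
#'   shift is `effect_size_d * sd_e`, so effect magnitudes vary across
#'   planted edges as they would across real tracts.
#' @param seed integer seed; the generator is a pure function of spec + seed.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_regions = 16,
                        n_per_group = c(20, 20),
                        baseline_edge_probability = 0.5,
                        attribute_means = c(cd = 0.012, fa = 0.5, md = 8e-4),
                        attribute_sds = c(cd = 0.003, fa = 0.05, md = 8e-5),
                        affected_edges = 10,
                        effect_size_d = 0,
                        affected_attributes = c("cd", "fa", "md"),
                        n_all = 10000,
                        edge_mean_cv = 0.35,
                        edge_sd_jitter = 0.5,
                        seed = 1L) {
  check_positive(n_regions, "n_regions", 1)
  check_positive(n_per_group, "n_per_group", 2)
  if (baseline_edge_probability <= 0 || baseline_edge_probability > 1) {
    stop_validation("baseline_edge_probability must be in (0, 1]")
  }
  for (nm in c("cd", "fa", "md")) {
    if (!nm %in% names(attribute_means) || attribute_means[[nm]] <= 0) {
      stop_validation(sprintf("attribute_means must include a positive '%s'", nm))
    }
    if (!nm %in% names(attribute_sds) || attribute_sds[[nm]] <= 0) {
      stop_validation(sprintf("attribute_sds must include a positive '%s'", nm))
    }
  }
  if (affected_edges < 0 || affected_edges != round(affected_edges)) {
    stop_validation("affected_edges must be a non-negative integer")
  }
  affected_attributes <- match.arg(affected_attributes, c("cd", "fa", "md"),
                                   several.ok = TRUE)
  n_edges <- n_regions * (n_regions - 1) / 2
  if (affected_edges > n_edges) {
    stop_validation("affected_edges exceeds the number of possible edges")
  }
  if (edge_mean_cv < 0 || edge_sd_jitter < 0 || edge_sd_jitter >= 1) {
    stop_validation("edge_mean_cv must be >= 0 and edge_sd_jitter in [0, 1)")
  }
  structure(list(n_regions = as.integer(n_regions),
                 n_per_group = as.integer(n_per_group),
                 baseline_edge_probability = baseline_edge_probability,
                 attribute_means = attribute_means,
                 attribute_sds = attribute_sds,
                 affected_edges = as.integer(affected_edges),
                 effect_size_d = effect_size_d,
                 affected_attributes = affected_attributes,
                 n_all = as.integer(n_all),
                 edge_mean_cv = edge_mean_cv,
                 edge_sd_jitter = edge_sd_jitter,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort of connectivity networks
#'
#' Deterministic given `spec` (including its seed). The identity of the
#' planted edges is returned for recovery testing. Missing edges are exact 0
#' in all attributes; FA draws are clipped to `[0, 1]`; each subject's total
#' density over present edges is renormalized to 1 whenever it would exceed 1.
#'
#' @param spec a [cohort_spec()].
#' @return an object of class `cohort_dataset`: list with `networks` (list of
#'   [connectivity_network()]), `labels` (factor, `group1`/`group2`),
#'   `planted_edges` (matrix of region pairs), `present_edges`, `n_regions`,
#'   `spec`.
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  r <- spec$n_regions
  idx <- edge_index_pairs(r)
  n_edges <- nrow(idx)
  n1 <- spec$n_per_group[1]
  n2 <- spec$n_per_group[2]

  with_seed(spec$seed, {
    present <- runif(n_edges) < spec$baseline_edge_probability
    if (!any(present)) present[1] <- TRUE
    present_ids <- which(present)
    if (spec$affected_edges > length(present_ids)) {
      stop_validation("affected_edges exceeds the number of present edges")
    }
    planted <- sort(sample(present_ids, spec$affected_edges))

    mu <- spec$attribute_means
    sds <- spec$attribute_sds
    shift <- spec$effect_size_d
    n_present <- sum(present)

    # per-edge baselines and spreads, drawn once and shared by all subjects
    cv <- spec$edge_mean_cv
    edge_means <- list(
      cd = exp(rnorm(n_present, log(mu[["cd"]]), sqrt(log(1 + cv^2)))),
      fa = pmin(pmax(rnorm(n_present, mu[["fa"]], cv * mu[["fa"]]), 0.1), 0.9),
      md = pmax(rnorm(n_present, mu[["md"]], cv * mu[["md"]]), 0.1 * mu[["md"]])
    )
    edge_sds <- lapply(c(cd = "cd", fa = "fa", md = "md"), function(nm) {
      sds[[nm]] * runif(n_present, 1 - spec$edge_sd_jitter, 1 + spec$edge_sd_jitter)
    })
    planted_pos <- match(planted, present_ids)

    make_subject <- function(group) {
      vals <- list()
      for (nm in c("cd", "fa", "md")) {
        x <- numeric(n_edges)
        x[present] <- rnorm(n_present, mean = edge_means[[nm]], sd = edge_sds[[nm]])
        if (group == 2L && nm %in% spec$affected_attributes) {
          x[planted] <- x[planted] + shift * edge_sds[[nm]][planted_pos]
        }
        x[present] <- pmax(x[present], 1e-9)  # attributes are positive quantities
        if (nm == "fa") x <- pmin(x, 1)
        vals[[nm]] <- x
      }
      tot <- sum(vals$cd)
      if (tot > 1) vals$cd <- vals$cd / tot
      counts_vec <- integer(n_edges)
      counts_vec[present] <- pmax(1L, as.integer(round(vals$cd[present] * spec$n_all)))
      to_mat <- function(x) {
        m <- matrix(0, r, r)
        m[idx] <- x
        m + t(m)
      }
      counts <- to_mat(counts_vec)
      net <- connectivity_network(counts, spec$n_all, to_mat(vals$fa),
                                  to_mat(vals$md), m = 1)
      # planted densities, not derived ones: overwrite cd with the drawn values
      net$density <- to_mat(vals$cd)
      net
    }

    networks <- c(lapply(seq_len(n1), function(i) make_subject(1L)),
                  lapply(seq_len(n2), function(i) make_subject(2L)))
    labels <- factor(rep(c("group1", "group2"), c(n1, n2)),
                     levels = c("group1", "group2"))
    structure(list(networks = networks, labels = labels,
                   planted_edges = idx[planted, , drop = FALSE],
                   present_edges = idx[present_ids, , drop = FALSE],
                   n_regions = r, spec = spec),
              class = "cohort_dataset")
  })
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf("cohort_dataset: %d + %d subjects, %d regions, %d present edges, %d planted (d = %g)\n",
              sum(x$labels == levels(x$labels)[1]),
              sum(x$labels == levels(x$labels)[2]),
              x$n_regions, nrow(x$present_edges), nrow(x$planted_edges),
              x$spec$effect_size_d))
  invisible(x)
}

#' Write a cohort as per-subject CSV edge lists plus a JSON manifest
#'
#' @param cohort a [make_cohort()] result (or compatible `cohort_dataset`).
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_cohort_csv <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  subjects <- sprintf("subject_%03d", seq_along(cohort$networks))
  for (s in seq_along(cohort$networks)) {
    net <- cohort$networks[[s]]
    idx <- edge_index_pairs(net$n_regions)
    df <- data.frame(region_i = idx[, 1], region_j = idx[, 2],
                     count = net$counts[idx], cd = net$density[idx],
                     fa = net$fa[idx], md = net$md[idx])
    write.csv(df, file.path(dir, paste0(subjects[s], ".csv")), row.names = FALSE)
  }
  manifest <- list(
    subjects = data.frame(id = subjects, group = as.character(cohort$labels)),
    n_regions = cohort$n_regions,
    n_all = vapply(cohort$networks, function(n) n$n_all, 0L),
    seed = if (!is.null(cohort$spec)) cohort$spec$seed else NA_integer_,
    planted_edges = as.data.frame(cohort$planted_edges)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort written by [write_cohort_csv()]
#'
#' @param dir cohort directory containing `manifest.json` and per-subject CSVs.
#' @return a `cohort_dataset`.
#' @export
read_cohort_csv <- function(dir) {
  man_path <- file.path(dir, "manifest.json")
  if (!file.exists(man_path)) stop_parse(paste("missing cohort manifest:", man_path))
  man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  r <- man$n_regions
  idx <- edge_index_pairs(r)
  networks <- vector("list", nrow(man$subjects))
  for (s in seq_len(nrow(man$subjects))) {
    path <- file.path(dir, paste0(man$subjects$id[s], ".csv"))
    df <- read.csv(path)
    need <- c("region_i", "region_j", "count", "cd", "fa", "md")
    if (!all(need %in% names(df))) {
      stop_parse(sprintf("cohort file '%s' lacks columns %s", path,
                         paste(setdiff(need, names(df)), collapse = ", ")))
    }
    to_mat <- function(x) {
      m <- matrix(0, r, r)
      m[cbind(df$region_i, df$region_j)] <- x
      m + t(m)
    }
    n_all <- if (length(man$n_all) >= s) man$n_all[s] else sum(df$count)
    net <- connectivity_network(to_mat(df$count), n_all, to_mat(df$fa),
                                to_mat(df$md), m = 1)
    net$density <- to_mat(df$cd)
    networks[[s]] <- net
  }
  planted <- as.matrix(man$planted_edges)
  structure(list(networks = networks,
                 labels = factor(man$subjects$group),
                 planted_edges = planted,
                 present_edges = NULL,
                 n_regions = r, spec = NULL),
            class = "cohort_dataset")
}
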