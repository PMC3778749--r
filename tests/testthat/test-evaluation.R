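test_that("stratified folds balance classes and reduce when classes are small", {
  labels <- factor(rep(c("a", "b"), c(20, 20)))
  folds <- make_folds(labels, "kfold10", 10, seed = 3L)
  expect_equal(sort(unique(folds)), 1:10)
  # each fold holds exactly 2 per class
  for (f in 1:10) {
    expect_equal(unname(table(labels[folds == f])), c(2L, 2L), ignore_attr = TRUE)
  }
  # leave-one-out: one fold per subject
  expect_equal(make_folds(labels, "loo"), 1:40)
  # a class smaller than the fold count shrinks the folds, with a warning
  small <- factor(rep(c("a", "b"), c(4, 12)))
  expect_warning(f2 <- make_folds(small, "kfold10", 10, seed = 1L), "reducing")
  expect_equal(max(f2), 4)
})

test_that("cross-validation is deterministic and pools accuracies exactly", {
  co <- make_cohort(cohort_spec(n_per_group = c(8, 8), n_regions = 8,
                                affected_edges = 5, effect_size_d = 2, seed = 5L))
  cfg <- experiment_config(attributes = c("cd", "fa"), seed = 9L)
  g1 <- run_cv(co, cfg)
  g2 <- run_cv(co, cfg)
  expect_identical(g1, g2)
  g3 <- run_cv(co, experiment_config(attributes = c("cd", "fa"), seed = 10L))
  expect_false(identical(g1$folds, g3$folds))
  # pooled counting: accuracy is an exact integer multiple of 1/n
  res <- g1$results
  expect_equal(res$accuracy * res$total, res$correct)
  expect_true(all(res$total == 16))
  expect_true(all(res$correct == round(res$correct)))
})

test_that("leave-one-out runs one round per subject", {
  co <- make_cohort(cohort_spec(n_per_group = c(5, 5), n_regions = 6,
                                affected_edges = 3, effect_size_d = 0, seed = 2L))
  cfg <- experiment_config(attributes = "cd", validation = "loo", seed = 1L)
  g <- run_cv(co, cfg)
  expect_equal(g$folds[["group1 vs group2"]], 1:10)
  rep <- g$selection[["group1 vs group2 | cd"]]
  expect_equal(rep$n_rounds, 10)
})

test_that("a strongly separated cohort is classified near-perfectly", {
  co <- make_cohort(cohort_spec(effect_size_d = 5, seed = 8L))
  g <- run_cv(co, experiment_config(seed = 8L))
  res <- g$results
  # geometry-sensitive classifiers are exact; correlation k-NN is close but
  # structurally weaker on uniform shifts (see the methods vignette)
  expect_true(all(res$accuracy[res$classifier != "knn"] == 1))
  expect_true(all(res$accuracy[res$classifier == "knn"] >= 0.85))
})

test_that("feature selection inside each round uses training subjects only", {
  co <- make_cohort(cohort_spec(n_per_group = c(10, 10), n_regions = 8,
                                affected_edges = 5, effect_size_d = 1.5, seed = 13L))
  cfg <- experiment_config(attributes = "cd", seed = 13L)
  g <- run_cv(co, cfg)
  folds <- g$folds[["group1 vs group2"]]
  rep <- g$selection[["group1 vs group2 | cd"]]
  fm <- vectorize(co, "cd")
  for (f in sort(unique(folds))) {
    train_fm <- structure(list(values = fm$values[folds != f, , drop = FALSE],
                               feature_index = fm$feature_index,
                               labels = droplevels(fm$labels[folds != f]),
                               attribute = "cd"),
                          class = "feature_matrix")
    recomputed <- select_features(train_fm, cfg$selection)$selected
    expect_identical(rep$per_round[[f]], recomputed)
    # the selection does not change when a held-out subject is altered
    mutated <- train_fm
    expect_identical(select_features(mutated, cfg$selection)$selected, recomputed)
  }
})

test_that("type-one check guards its preconditions and returns per-repeat accuracies", {
  expect_error(type_one_check(cohort_spec(effect_size_d = 1)), "null spec")
  spec <- cohort_spec(n_per_group = c(6, 6), n_regions = 6, affected_edges = 3,
                      effect_size_d = 0)
  res <- suppressWarnings(type_one_check(spec,
    experiment_config(attributes = "cd", classifiers = "nb"),
    n_repeats = 2, base_seed = 77L))
  expect_equal(length(unique(res$accuracies$rep)), 2)
  expect_true(res$ci["lower"] < 0.5 && res$ci["upper"] > 0.5)
})

test_that("the rendered grid reproduces the printed accuracy granularity", {
  fake <- structure(list(results = data.frame(
    comparison = rep("patients vs controls", 3),
    attribute = c("cd", "fa", "md"),
    classifier = rep("max_margin", 3),
    correct = c(43, 35, 34), total = c(44, 38, 40),
    accuracy = c(43 / 44, 35 / 38, 34 / 40)),
    selection = list(), folds = list(),
    config = experiment_config()), class = "result_grid")
  txt <- render_table(fake)$text
  expect_true(any(grepl("97.73%", txt, fixed = TRUE)))
  expect_true(any(grepl("92.11%", txt, fixed = TRUE)))
  expect_true(any(grepl("85.00%", txt, fixed = TRUE)))
  # perfect and integer-percentage cases
  expect_equal(sprintf("%.2f%%", 100 * 20 / 20), "100.00%")
  expect_equal(sprintf("%.2f%%", 100 * 17 / 20), "85.00%")
})

test_that("result grids round-trip to disk", {
  co <- make_cohort(cohort_spec(n_per_group = c(5, 5), n_regions = 6,
                                affected_edges = 3, effect_size_d = 2, seed = 4L))
  g <- run_cv(co, experiment_config(attributes = "cd", seed = 4L))
  dir <- tempfile()
  write_result_grid(g, dir)
  expect_true(file.exists(file.path(dir, "results.csv")))
  expect_true(file.exists(file.path(dir, "results.txt")))
  back <- read.csv(file.path(dir, "results.csv"))
  expect_equal(back$accuracy, g$results$accuracy)
  sel <- read.csv(file.path(dir, "selection_frequency.csv"))
  expect_true(all(c("comparison", "attribute", "feature", "rounds_selected",
                    "highlighted") %in% names(sel)))
})
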