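#' Experiment configuration for cross-validated network classification
#'
#' @param comparisons list of two-element character vectors of group labels to
#'   compare; `NULL` means all pairs of levels present in the cohort.
#' @param attributes subset of `c("cd", "fa", "md")`.
#' @param classifiers subset of `c("max_margin", "knn", "nb")`.
#' @param validation `"kfold10"` (stratified 10-fold) or `"loo"`
#'   (leave-one-out).
#' @param n_folds fold count for k-fold validation, default 10.
#' @param seed integer seed for the stratified fold shuffle (the only source
#'   of randomness in the harness).
#' @param selection `"all_positive"` or an integer `top_n`, passed to
#'   [select_features()].
#' @param round_threshold strict round-count threshold for highlighting
#'   selected edges, default 5.
#' @param knn_k neighbors for the k-NN classifier, default 6.
#' @param cost SVM penalty C, default 1.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(comparisons = NULL,
                              attributes = c("cd", "fa", "md"),
                              classifiers = c("max_margin", "knn", "nb"),
                              validation = c("kfold10", "loo"),
                              n_folds = 10,
                              seed = 1L,
                              selection = "all_positive",
                              round_threshold = 5,
                              knn_k = 6,
                              cost = 1) {
  validation <- match.arg(validation)
  attributes <- match.arg(attributes, c("cd", "fa", "md"), several.ok = TRUE)
  classifiers <- match.arg(classifiers, c("max_margin", "knn", "nb"),
                           several.ok = TRUE)
  check_positive(n_folds, "n_folds", 1)
  structure(list(comparisons = comparisons, attributes = attributes,
                 classifiers = classifiers, validation = validation,
                 n_folds = as.integer(n_folds), seed = as.integer(seed),
                 selection = selection, round_threshold = round_threshold,
                 knn_k = as.integer(knn_k), cost = cost),
            class = "experiment_config")
}

#' Stratified cross-validation fold assignment
#'
#' Subjects of each class are shuffled (seeded) and dealt round-robin into
#' folds, so every fold is as class-balanced as the group sizes allow. If a
#' class has fewer members than `n_folds`, the fold count is reduced to the
#' smallest class size, with a warning. Leave-one-out assigns each subject its
#' own fold.
#'
#' @param labels factor of class labels.
#' @param validation `"kfold10"` or `"loo"`.
#' @param n_folds fold count for k-fold.
#' @param seed shuffle seed.
#' @return integer vector of fold ids per subject.
#' @export
make_folds <- function(labels, validation = "kfold10", n_folds = 10, seed = 1L) {
  n <- length(labels)
  if (validation == "loo") return(seq_len(n))
  smallest <- min(table(droplevels(as.factor(labels))))
  if (smallest < n_folds) {
    warning(sprintf("smallest class has %d members: reducing folds from %d to %d",
                    smallest, n_folds, smallest))
    n_folds <- smallest
  }
  folds <- integer(n)
  with_seed(seed, {
    for (cl in levels(droplevels(as.factor(labels)))) {
      members <- which(labels == cl)
      members <- members[sample.int(length(members))]
      folds[members] <- rep_len(seq_len(n_folds), length(members))
    }
  })
  folds
}

train_and_predict <- function(classifier, x_train, y_train, x_test, config) {
  model <- switch(classifier,
    max_margin = train_max_margin(x_train, y_train, cost = config$cost),
    knn = train_knn(x_train, y_train, k = min(config$knn_k, nrow(x_train))),
    nb = train_nb(x_train, y_train))
  pred <- switch(classifier,
    max_margin = predict_max_margin(model, x_test),
    knn = predict_knn(model, x_test),
    nb = predict_nb(model, x_test))
  pred
}

#' Run the cross-validated classification protocol on a cohort
#'
#' For every comparison and every attribute, subjects are split into
#' stratified folds; within each round, information-gain feature selection and
#' classifier training use only the training subjects (a degenerate empty
#' selection falls back to all features), and the held-out subjects are
#' predicted once each. Accuracies are pooled across rounds as total correct
#' over total subjects, so every reported accuracy is an integer multiple of
#' `1/n_subjects`. The entire run is deterministic given the config seed.
#'
#' @param cohort a `cohort_dataset`.
#' @param config an [experiment_config()].
#' @return an object of class `result_grid`: list with `results` (data frame
#'   of comparison x attribute x classifier accuracies with pooled counts),
#'   `selection` (named list of [aggregate_selection()] reports per
#'   comparison x attribute), `folds` (per comparison), `config`.
#' @export
run_cv <- function(cohort, config = experiment_config()) {
  stopifnot(inherits(cohort, "cohort_dataset"), inherits(config, "experiment_config"))
  lv <- levels(droplevels(cohort$labels))
  comparisons <- config$comparisons
  if (is.null(comparisons)) {
    comparisons <- utils::combn(lv, 2, simplify = FALSE)
  }
  rows <- list()
  selection_reports <- list()
  fold_record <- list()
  idx_pairs <- edge_index_pairs(cohort$n_regions)

  for (comp in comparisons) {
    keep <- cohort$labels %in% comp
    if (min(table(factor(cohort$labels[keep], levels = comp))) < 2) {
      stop_validation("each class in a comparison needs at least 2 subjects")
    }
    sub_labels <- factor(as.character(cohort$labels[keep]), levels = comp)
    sub_cohort <- structure(list(networks = cohort$networks[keep],
                                 labels = sub_labels,
                                 n_regions = cohort$n_regions),
                            class = "cohort_dataset")
    folds <- make_folds(sub_labels, config$validation, config$n_folds, config$seed)
    comp_name <- paste(comp, collapse = " vs ")
    fold_record[[comp_name]] <- folds
    n_sub <- length(sub_labels)

    for (attr in config$attributes) {
      fm <- vectorize(sub_cohort, attr)
      correct <- setNames(integer(length(config$classifiers)), config$classifiers)
      round_selections <- list()
      for (fold in sort(unique(folds))) {
        test <- folds == fold
        train_fm <- structure(list(values = fm$values[!test, , drop = FALSE],
                                   feature_index = fm$feature_index,
                                   labels = droplevels(fm$labels[!test]),
                                   attribute = attr),
                              class = "feature_matrix")
        sel <- select_features(train_fm, config$selection)
        round_selections[[length(round_selections) + 1L]] <- sel$selected
        use <- if (length(sel$selected) == 0) seq_len(ncol(fm$values)) else sel$selected
        x_train <- fm$values[!test, use, drop = FALSE]
        x_test <- fm$values[test, use, drop = FALSE]
        for (clf in config$classifiers) {
          pred <- train_and_predict(clf, x_train, fm$labels[!test], x_test, config)
          correct[clf] <- correct[clf] + sum(as.character(pred) ==
                                               as.character(fm$labels[test]))
        }
      }
      selection_reports[[paste(comp_name, attr, sep = " | ")]] <-
        aggregate_selection(round_selections, ncol(fm$values), idx_pairs,
                            config$round_threshold)
      for (clf in config$classifiers) {
        rows[[length(rows) + 1L]] <- data.frame(
          comparison = comp_name, attribute = attr, classifier = clf,
          correct = correct[clf], total = n_sub,
          accuracy = correct[clf] / n_sub, row.names = NULL)
      }
    }
  }
  structure(list(results = do.call(rbind, rows),
                 selection = selection_reports,
                 folds = fold_record,
                 config = config),
            class = "result_grid")
}

#' @export
print.result_grid <- function(x, ...) {
  cat(render_table(x)$text, sep = "\n")
  invisible(x)
}

#' Null-protocol validity check
#'
#' Monte-Carlo check that the nested-selection cross-validation protocol has
#' no optimistic bias: cohorts generated under the null (`effect_size_d = 0`)
#' must yield pooled accuracies consistent with chance. Returns per-repeat
#' accuracies and the 95% binomial interval around 0.5 for the total number
#' of pooled predictions.
#'
#' @param spec a [cohort_spec()] with `effect_size_d = 0`.
#' @param config an [experiment_config()] (a single comparison results from
#'   the two-group cohorts).
#' @param n_repeats number of null cohorts, each with its own seed.
#' @param base_seed first cohort seed; repeat r uses `base_seed + r - 1`.
#' @return list with `accuracies` (data frame: repeat, classifier, attribute,
#'   accuracy), `mean_accuracy` (per classifier), `ci` (binomial interval),
#'   `n_predictions`.
#' @export
type_one_check <- function(spec, config = experiment_config(attributes = "cd"),
                           n_repeats = 50, base_seed = 1000L) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$effect_size_d != 0) stop_validation("type_one_check requires a null spec (effect_size_d = 0)")
  check_positive(n_repeats, "n_repeats", 1)
  acc <- list()
  for (r in seq_len(n_repeats)) {
    s <- spec
    s$seed <- as.integer(base_seed + r - 1)
    cohort <- make_cohort(s)
    if (length(unique(cohort$labels)) < 2) stop_validation("cohort labels are constant")
    cfg <- config
    cfg$seed <- as.integer(base_seed + r - 1)
    grid <- run_cv(cohort, cfg)
    res <- grid$results
    res$rep <- r
    acc[[r]] <- res
  }
  all_res <- do.call(rbind, acc)
  n_per_rep <- sum(spec$n_per_group)
  n_total <- n_per_rep * n_repeats
  mean_acc <- tapply(all_res$accuracy, all_res$classifier, mean)
  half <- qnorm(0.975) * sqrt(0.25 / n_total)
  list(accuracies = all_res,
       mean_accuracy = mean_acc,
       ci = c(lower = 0.5 - half, upper = 0.5 + half),
       n_predictions = n_total)
}

#' Format a result grid in the 3 x 3 accuracy-table layout
#'
#' One block per comparison with attribute rows and classifier columns;
#' accuracies printed as percentages to two decimals (pooled counting makes
#' each an integer multiple of `1/n_subjects`).
#'
#' @param grid a `result_grid`.
#' @return list with `text` (character lines) and `table` (wide data frame).
#' @export
render_table <- function(grid) {
  stopifnot(inherits(grid, "result_grid"))
  res <- grid$results
  attr_names <- c(cd = "Fiber density", fa = "FA", md = "MD")
  clf_names <- c(max_margin = "SVM", knn = "k-NN", nb = "Naive Bayes")
  lines <- character(0)
  wide_rows <- list()
  for (comp in unique(res$comparison)) {
    sub <- res[res$comparison == comp, ]
    lines <- c(lines, sprintf("%s (n = %d)", comp, sub$total[1]))
    clfs <- unique(sub$classifier)
    header <- sprintf("%-14s %s", "", paste(sprintf("%-12s", clf_names[clfs]),
                                            collapse = ""))
    lines <- c(lines, header)
    for (attr in unique(sub$attribute)) {
      row <- sub[sub$attribute == attr, ]
      accs <- vapply(clfs, function(cl)
        sprintf("%.2f%%", 100 * row$accuracy[row$classifier == cl]), "")
      lines <- c(lines, sprintf("%-14s %s", attr_names[attr],
                                paste(sprintf("%-12s", accs), collapse = "")))
      wide <- as.list(setNames(row$accuracy[match(clfs, row$classifier)], clfs))
      wide_rows[[length(wide_rows) + 1L]] <-
        data.frame(comparison = comp, attribute = attr, wide,
                   total = row$total[1])
    }
    lines <- c(lines, "")
  }
  list(text = lines, table = do.call(rbind, wide_rows))
}

#' Write a result grid to disk
#'
#' Writes `results.csv` (long format), `results.txt` (formatted table layout)
#' and `selection_frequency.csv` (per comparison x attribute x edge round
#' counts).
#'
#' @param grid a `result_grid`.
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_result_grid <- function(grid, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(grid$results, file.path(dir, "results.csv"), row.names = FALSE)
  writeLines(render_table(grid)$text, file.path(dir, "results.txt"))
  sel_rows <- list()
  for (nm in names(grid$selection)) {
    rep <- grid$selection[[nm]]
    idx <- which(rep$counts > 0)
    if (length(idx)) {
      parts <- strsplit(nm, " | ", fixed = TRUE)[[1]]
      sel_rows[[nm]] <- data.frame(comparison = parts[1], attribute = parts[2],
                                   feature = idx, rounds_selected = rep$counts[idx],
                                   highlighted = idx %in% rep$highlighted)
    }
  }
  sel <- if (length(sel_rows)) do.call(rbind, sel_rows) else
    data.frame(comparison = character(0), attribute = character(0),
               feature = integer(0), rounds_selected = integer(0),
               highlighted = logical(0))
  write.csv(sel, file.path(dir, "selection_frequency.csv"), row.names = FALSE)
  jsonlite::write_json(list(seed = grid$config$seed,
                            validation = grid$config$validation,
                            selection = grid$config$selection),
                       file.path(dir, "run.json"), auto_unbox = TRUE)
  invisible(dir)
}
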