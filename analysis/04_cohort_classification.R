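#!/usr/bin/env Rscript
# Classify synthetic two-group cohorts of connectivity networks with the full
# protocol: information-gain feature selection nested in stratified 10-fold
# (and leave-one-out) cross-validation, three classifiers, three edge
# attributes. Produces the 3 x 3 accuracy grid and the selection-frequency
# report for a cohort with a planted group difference.

library(iscn)

out <- "results/classification"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 2026L

spec <- cohort_spec(effect_size_d = 2, seed = seed)
cohort <- make_cohort(spec)
write_cohort_csv(cohort, file.path(out, "cohort"))
cat("Cohort: "); print(cohort)

grid10 <- run_cv(cohort, experiment_config(validation = "kfold10", seed = seed))
write_result_grid(grid10, file.path(out, "kfold10"))
cat("\n10-fold cross-validation, pooled accuracies:\n")
cat(render_table(grid10)$text, sep = "\n")

grid_loo <- run_cv(cohort, experiment_config(validation = "loo", seed = seed))
write_result_grid(grid_loo, file.path(out, "loo"))
cat("Leave-one-out validation:\n")
cat(render_table(grid_loo)$text, sep = "\n")

# how often does the selection highlight truly planted edges?
keys <- apply(iscn:::edge_index_pairs(cohort$n_regions), 1, paste, collapse = "-")
planted <- match(apply(cohort$planted_edges, 1, paste, collapse = "-"), keys)
for (nm in names(grid10$selection)) {
  rep <- grid10$selection[[nm]]
  if (length(rep$highlighted)) {
    cat(sprintf("%s: %d edges selected in >%d rounds, %.0f%% of them planted\n",
                nm, length(rep$highlighted), rep$round_threshold,
                100 * mean(rep$highlighted %in% planted)))
  }
}
cat("\nEdges selected in more than 5 of the 10 rounds almost exclusively\n",
    "coincide with the planted group difference; the maximum-margin and\n",
    "naive Bayes classifiers recover the groups nearly perfectly, while\n",
    "correlation-based k-NN is weaker because a uniform standardized shift\n",
    "is largely invisible to Pearson similarity (see the methods vignette).\n",
    sep = "")
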