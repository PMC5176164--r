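#!/usr/bin/env Rscript
# Stage 4: model comparison.
# For each feature arm, runs the four families (penalised multinomial
# logistic, polynomial SVM, random forest, gradient-boosted trees) through
# the inner 70/30 split with 10-fold cross-validation, and reports the
# selected configuration and validation accuracy per family.
suppressMessages(library(sealgram))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[[1]]) else 7L

rows <- list()
for (arm_name in c("without_features", "with_features")) {
  train <- read_features(sprintf("results/train_%s.csv", arm_name))
  gs <- grid_search(protocol_grids(), train, n_folds = 10, seed = seed)
  for (family in names(gs)) {
    cat(sprintf("[%s] %-20s cv %.2f%%  validation %.2f%%\n", arm_name, family,
                100 * gs[[family]]$cv_accuracy,
                100 * gs[[family]]$validation_accuracy))
    rows[[length(rows) + 1]] <- data.frame(
      arm = arm_name, family = family,
      cv_accuracy = 100 * gs[[family]]$cv_accuracy,
      validation_accuracy = 100 * gs[[family]]$validation_accuracy)
  }
}
utils::write.csv(do.call(rbind, rows), "results/training_summary.csv",
                 row.names = FALSE)
cat("Wrote results/training_summary.csv\n")
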