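#!/usr/bin/env Rscript
# Stage 5: leave-two-subjects-out evaluation.
# Refits each family's selected configuration on the full (under-sampled)
# training subjects and scores the two held-out animals: confusion
# matrices, overall accuracy and per-class sensitivity, per feature arm.
# This is the cross-validation question the study design answers: how well
# do the models generalise to animals they have never seen?
suppressMessages(library(sealgram))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[[1]]) else 7L

rows <- list()
for (arm_name in c("without_features", "with_features")) {
  train <- read_features(sprintf("results/train_%s.csv", arm_name))
  hold <- read_features(sprintf("results/holdout_%s.csv", arm_name))
  grids <- protocol_grids()
  for (family in names(grids)) {
    args_f <- grids[[family]][[1]]
    cfg <- model_config(family, kernel = args_f$kernel,
                        hyperparameters = args_f$hyperparameters,
                        seed = derive_seed(seed, paste0(family, "/final")))
    m <- fit_model(cfg, train)
    pred <- predict_model(m, hold)
    cm <- confusion(pred$class, hold$category)
    met <- cm_metrics(cm)
    cat(sprintf("[%s] %-20s holdout accuracy %.2f%%  sens (f/g/r/t): %s\n",
                arm_name, family, met$accuracy,
                paste(sprintf("%.1f", met$sensitivity), collapse = "/")))
    utils::write.csv(as.data.frame.matrix(cm),
                     sprintf("results/cm_%s_%s.csv", arm_name, family))
    rows[[length(rows) + 1]] <- data.frame(
      arm = arm_name, family = family, accuracy = met$accuracy,
      t(met$sensitivity), row.names = NULL)
  }
}
summary <- do.call(rbind, rows)
utils::write.csv(summary, "results/holdout_summary.csv", row.names = FALSE)

best <- summary[which.max(summary$accuracy), ]
cat(sprintf("\nBest holdout model: %s (%s), %.2f%% accuracy\n",
            best$family, best$arm, best$accuracy))
cat("Wrote results/holdout_summary.csv and per-model confusion matrices\n")
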