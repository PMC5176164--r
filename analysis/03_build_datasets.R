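#!/usr/bin/env Rscript
# Stage 3: dataset assembly.
# Splits epochs by subject (two held out: one female sea lion, one male fur
# seal), encodes place and optional subject covariates, and under-samples
# the training classes to the 3000-epoch cap. Writes train/holdout tables
# per feature arm and a split manifest.
suppressMessages(library(sealgram))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[[1]]) else 7L

features <- read_features("results/features.csv")
cohort <- utils::read.csv("results/sessions/cohort.csv", stringsAsFactors = FALSE)

sp <- split_subjects(features, cohort, seed = seed)
cat("Held-out subjects:", paste(sp$holdout_subjects, collapse = ", "), "\n")
print(cohort[cohort$subject_id %in% sp$holdout_subjects, ])

for (arm in c(FALSE, TRUE)) {
  arm_name <- if (arm) "with_features" else "without_features"
  train <- attach_subject_features(sp$train, cohort, enabled = arm)
  hold <- attach_subject_features(sp$holdout, cohort, enabled = arm)
  before <- table(train$category)
  train <- undersample(train, class_cap = 3000, seed = seed)
  cat(sprintf("[%s] train %d -> %d epochs (cap 3000), holdout %d epochs (untouched)\n",
              arm_name, sum(before), nrow(train), nrow(hold)))
  write_features(train, sprintf("results/train_%s.csv", arm_name))
  write_features(hold, sprintf("results/holdout_%s.csv", arm_name))
}

jsonlite::write_json(
  list(seed = seed, holdout_subjects = sp$holdout_subjects,
       train_subjects = setdiff(cohort$subject_id, sp$holdout_subjects)),
  "results/split_manifest.json", auto_unbox = TRUE, pretty = TRUE)
cat("Wrote train/holdout tables and results/split_manifest.json\n")
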