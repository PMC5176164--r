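#!/usr/bin/env Rscript
# Stage 2: feature extraction.
# Reads the session CSVs from stage 1, decomposes each trace into static and
# dynamic acceleration (3 s running mean), summarises non-overlapping
# 13-sample epochs into the 52 movement statistics, labels epochs by
# majority category (precedence on ties), drops 'other', and writes one
# labelled feature table.
suppressMessages(library(sealgram))

files <- list.files("results/sessions", pattern = "^session_.*\\.csv$",
                    full.names = TRUE)
stopifnot(length(files) > 0)

tables <- lapply(files, function(f) {
  s <- read_session(f)
  dec <- decompose_acceleration(s$trace)
  ft <- epoch_features(dec, s$trace, epoch_len = 13, stride = 13)
  label_epochs(ft, s$labels)
})
features <- do.call(rbind, c(tables, make.row.names = FALSE))
attr(features, "epoch_len") <- 13L; attr(features, "stride") <- 13L
write_features(features, "results/features.csv")

cat("Featurized", length(files), "sessions ->", nrow(features),
    "labelled epochs x", length(feature_names()), "statistics\n")
cat("Epoch category counts:\n")
print(table(features$category))
cat("Wrote results/features.csv\n")
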