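#!/usr/bin/env Rscript
# Stage 6: published-arithmetic audit (needs no inputs).
# Recomputes overall accuracy and all per-class sensitivities from the four
# published cross-validation confusion matrices and checks them against the
# printed values; specificity rows are informational (no single formula
# reproduces the printed column) and disagreements are catalogued.
suppressMessages(library(sealgram))

rep_df <- reproduce_printed_metrics()
utils::write.csv(rep_df, "results/printed_metrics_report.csv", row.names = FALSE)

exact <- rep_df[rep_df$quantity %in% c("accuracy", "sensitivity"), ]
cat(sprintf("Exact checks (accuracy + sensitivity): %d/%d pass\n",
            sum(exact$pass), nrow(exact)))
spec <- rep_df[rep_df$quantity == "specificity", ]
cat(sprintf("Informational specificity comparisons: %d/%d agree, %d catalogued discrepancies\n",
            sum(spec$pass), nrow(spec), sum(!spec$pass)))
print(rep_df[rep_df$quantity == "accuracy", c("model", "computed", "printed", "pass")])
cat("Wrote results/printed_metrics_report.csv\n")
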