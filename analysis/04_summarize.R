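#!/usr/bin/env Rscript

# Summary artifacts from the grid results: group-wise mean accuracies,
# counts of recordings above 75% accuracy, within-class accuracy
# distributions, and the feature-selection heatmap, plus the comparison of
# every cell against the above-chance thresholds.

suppressPackageStartupMessages({
  library(midecode)
  library(dplyr)
})

results <- as_tibble(read.csv("results/accuracies.csv"))
selections <- as_tibble(read.csv("results/selections.csv"))
crit <- as_tibble(read.csv("results/chance_criteria.csv"))

summ <- summarize_results(results, selections = selections, threshold = 0.75)
write.csv(summ$mean_accuracy, "results/mean_accuracy.csv", row.names = FALSE)
write.csv(summ$counts_above_threshold, "results/counts_above_075.csv",
  row.names = FALSE
)
write.csv(summ$within_class, "results/within_class.csv", row.names = FALSE)
write.csv(summ$selection_heatmap, "results/selection_heatmap.csv",
  row.names = FALSE
)

# also the first-sessions-only sensitivity variant of the mean table
first <- summarize_results(results, threshold = 0.75,
  first_sessions_only = TRUE
)
write.csv(first$mean_accuracy, "results/mean_accuracy_first_sessions.csv",
  row.names = FALSE
)

# flag above-chance cells at both thresholds
nominal <- crit$critical_count[crit$level == "nominal"]
corrected <- crit$critical_count[crit$level == "bonferroni_14"]
flagged <- results |>
  mutate(
    above_nominal = h0 >= nominal,
    above_corrected = h0 >= corrected
  )
write.csv(flagged, "results/accuracies_flagged.csv", row.names = FALSE)

cat("\nMean accuracy (%) by comparison and feature kind, across montages:\n")
summ$mean_accuracy |>
  group_by(comparison, feature_kind) |>
  summarise(mean = round(100 * mean(mean_accuracy), 1), .groups = "drop") |>
  tidyr::pivot_wider(names_from = feature_kind, values_from = mean) |>
  as.data.frame() |>
  print(row.names = FALSE)

cat(sprintf(
  "\ncells above the nominal chance threshold (H0 >= %d): %d of %d\n",
  nominal, sum(flagged$above_nominal), nrow(flagged)
))
cat(sprintf(
  "cells above the Bonferroni-corrected threshold (H0 >= %d): %d of %d\n",
  corrected, sum(flagged$above_corrected), nrow(flagged)
))
cat("\nSummary tables written under results/\n")
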