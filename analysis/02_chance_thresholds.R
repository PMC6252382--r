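#!/usr/bin/env Rscript

# Above-chance thresholds for the pooled test-set size used throughout:
# 300 segments (25 trials x 6 sub-segments per condition, balanced pair),
# maximum-chance criterion 150, at the nominal level and at the
# Bonferroni-corrected level for 7 comparisons x 2 feature kinds.

suppressPackageStartupMessages(library(midecode))

n <- 2 * 25 * 6
hc <- n / 2

nominal <- chance_criterion(hc, n, alpha = 0.05)
corrected <- chance_criterion(hc, n, alpha = bonferroni_alpha(0.05, 14))

print(nominal)
print(corrected)

tab <- data.frame(
  level = c("nominal", "bonferroni_14"),
  alpha = c(nominal$alpha, corrected$alpha),
  n = n, hc = hc,
  z_critical = c(nominal$z_critical, corrected$z_critical),
  critical_count = c(nominal$critical_count, corrected$critical_count),
  critical_accuracy = c(nominal$critical_accuracy, corrected$critical_accuracy)
)
dir.create("results", showWarnings = FALSE)
write.csv(tab, "results/chance_criteria.csv", row.names = FALSE)
message("thresholds written to results/chance_criteria.csv")
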