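#!/usr/bin/env Rscript
# Aggregate the per-cell records into condition summaries (mean R, 95% CI,
# percent positive) and test the enrichment contrast with one-way ANOVA
# plus a Bonferroni post-hoc comparison against the control.

library(opticr)

records <- read.csv("results/records.csv")
summary_df <- summarize_cohort(records)
res <- anova_with_bonferroni(split(records$R, records$condition),
                             reference = "control")

write.csv(summary_df, "results/summary.csv", row.names = FALSE)
write.csv(res$posthoc, "results/posthoc.csv", row.names = FALSE)
report <- c(
  sprintf("One-way ANOVA: F(%d, %d) = %.2f, p = %.3g",
          res$df_between, res$df_within, res$F_statistic, res$p_value),
  "Bonferroni post-hoc versus 'control':",
  capture.output(print(res$posthoc, row.names = FALSE))
)
writeLines(report, "results/anova_report.txt")
message(paste(report, collapse = "\n"))
print(summary_df, row.names = FALSE)
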