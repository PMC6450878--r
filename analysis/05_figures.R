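#!/usr/bin/env Rscript
# Figures for the cohort run: per-cell dot plot with mean and 95% CI,
# percent-positive bar chart, and a line-scan profile through the
# attachment site of one enriched field.

library(opticr)
library(ggplot2)

records <- read.csv("results/records.csv")
summary_df <- summarize_cohort(records)
dir.create("results/figures", recursive = TRUE, showWarnings = FALSE)

ggsave("results/figures/recruitment_dotplot.pdf",
       plot_recruitment(records, summary_df), width = 5, height = 4)
ggsave("results/figures/percent_positive.pdf",
       plot_percent_positive(summary_df), width = 4, height = 4)

sim <- simulate_field(optic_params(enrichment_factor = 3, seed = 7L))
ctr <- (dim(sim$field$channels$poi) - 1) / 2
cm <- which(sim$truth$cluster_mask, arr.ind = TRUE) - 1
centroid <- colMeans(cm)
p1 <- centroid + (centroid - ctr) * 0.4
prof <- line_scan(sim$field, ctr, p1, n_samples = 120)
long <- do.call(rbind, lapply(c("bacteria", "receptor", "poi"), function(ch)
  data.frame(position = prof$position, channel = ch, intensity = prof[[ch]])))
gg <- ggplot(long, aes(position, intensity, colour = channel)) +
  geom_line() +
  labs(x = "position along scan (px)", y = "intensity / max") +
  theme_classic()
ggsave("results/figures/line_scan.pdf", gg, width = 5, height = 3.5)
message("figures written to results/figures/")
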