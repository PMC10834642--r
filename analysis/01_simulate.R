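#!/usr/bin/env Rscript
# Stage 1 — synthesise the study: 20 root-extract batches measured at the
# reference UPLC condition (7 saikosaponin target peaks + 10 non-target
# common peaks per sample), plus one rendered chromatogram per channel for
# the first batch.

suppressPackageStartupMessages(library(saikoqams))
dir.create("results", showWarnings = FALSE)

cfg <- sim_config(seed = 101)
peaks <- simulate_study(cfg, seed = 11)
write_peak_table_csv(peaks, "results/peak_tables.csv")

message(sprintf("Simulated %d peaks across %d batches (%d per sample).",
                nrow(peaks), length(unique(peaks$sample_id)),
                nrow(peaks) / length(unique(peaks$sample_id))))

pt1 <- peaks[peaks$sample_id == "S1", ]
for (ch in c("210", "254")) {
  chrom <- simulate_chromatogram(cfg, pt1, channel = ch, seed = 21)
  utils::write.csv(data.frame(time_min = chrom$time,
                              intensity = round(chrom$intensity, 3)),
                   sprintf("results/chromatogram_S1_%snm.csv", ch),
                   row.names = FALSE)
}
message("Rendered S1 chromatograms at 210 and 254 nm (31 min, 0.01-min grid).")

g <- default_batches()
message(sprintf("Latitude bands: %s.",
                paste(sprintf("%s n=%d", names(table(g$group)),
                              table(g$group)), collapse = ", ")))
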