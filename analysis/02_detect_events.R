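#!/usr/bin/env Rscript
# Detect sharp-wave ripples (80-250 Hz envelope, 4 SD detect / 1 SD expand /
# 15 ms minimum) and dentate spikes (hilus-molecular difference with the
# 0.19 mV molecular criterion) on the simulated recording, and score them
# against the ground truth.  Writes results/events/*.csv.

suppressPackageStartupMessages(library(hippomap))
data_dir <- "results/data"
out <- "results/events"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

meta <- jsonlite::read_json(file.path(data_dir, "meta.json"),
                            simplifyVector = TRUE)
seg <- read_recording(file.path(data_dir, "recording.bin"),
                      file.path(data_dir, "recording.json"))
gt <- jsonlite::read_json(file.path(data_dir, "ground_truth.json"),
                          simplifyVector = TRUE)

rip <- detect_ripples(seg, meta$pyr_channel)
write_events(rip, file.path(out, "ripples.csv"))
err <- sapply(gt$ripples$peak, function(p) min(abs(rip$peak - p)) * 1000)
message(sprintf("ripples: %d detected / %d injected; recall(10 ms) = %.2f; median peak error %.1f ms",
                nrow(rip), nrow(gt$ripples), mean(err <= 10),
                stats::median(err[err <= 10])))

ds <- detect_dentate_spikes(seg, meta$hilus_channel, meta$molecular_channel)
write_events(ds, file.path(out, "dentate_spikes.csv"))
if (length(gt$ds_times)) {
  derr <- sapply(gt$ds_times, function(p) min(abs(ds$peak - p)) * 1000)
  message(sprintf("dentate spikes: %d detected / %d injected; max peak error %.1f ms",
                  nrow(ds), length(gt$ds_times), max(derr)))
} else message("dentate spikes: none injected")

summary <- data.frame(
  class = c("ripple", "dentate_spike"),
  injected = c(nrow(gt$ripples), length(gt$ds_times)),
  detected = c(nrow(rip), nrow(ds)))
utils::write.csv(summary, file.path(out, "detection_summary.csv"),
                 row.names = FALSE)
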