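#!/usr/bin/env Rscript
# Ripple-triggered average LFP and the laminar current source density along
# the shank: the sharp wave should appear as a radiatum sink flanked by
# passive sources.  Writes results/csd/*.csv (+ JSON axis sidecars).

suppressPackageStartupMessages(library(hippomap))
data_dir <- "results/data"
out <- "results/csd"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

seg <- read_recording(file.path(data_dir, "recording.bin"),
                      file.path(data_dir, "recording.json"))
probe <- read_probe_map(file.path(data_dir, "probe_map.json"))
rip <- read_events("results/events/ripples.csv")

avg <- event_triggered_average(seg, rip$peak, window_ms = c(-100, 100))
write_map_csv(avg, file.path(out, "ripple_triggered_lfp.csv"))
cs <- compute_csd(avg, probe, shank = 0, column = 0)
write_map_csv(cs, file.path(out, "ripple_triggered_csd.csv"))

at0 <- cs$values[, which.min(abs(cs$lag_ms))]
sink_row <- cs$rows[which.min(at0)]
rad <- default_layer_rows(max(probe$row) + 1L)$radiatum
message(sprintf("CSD sink at row %d (radiatum rows %d-%d): %s",
                sink_row, min(rad), max(rad),
                if (sink_row %in% rad) "as expected" else "UNEXPECTED"))
message(sprintf("flanking sources: %s",
                all(at0[which.min(at0) + c(-2, 2)] > 0)))
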