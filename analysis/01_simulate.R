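#!/usr/bin/env Rscript
# Generate the study's synthetic recording: a single-shank section of the
# 8-shank probe (32 electrode rows at the full 30 um pitch), 60 s at
# 10 kS/s, with sharp-wave ripples, dentate spikes, a radiatum gamma
# source, and three units (a gamma-coupled putative interneuron, a
# ripple-modulated pyramidal cell, and an uncoupled deep unit).  Writes the
# recording in the pipeline's flat-binary + JSON format together with the
# ground truth, under results/data/.

suppressPackageStartupMessages(library(hippomap))
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 20260923L

probe <- build_probe_map(n_shanks = 1L, n_rows = 32L)
layer <- default_layer_rows(32L)
ch_at <- function(row) probe$channel_id[probe$row == row & probe$column == 0][1]
pyr_ch <- ch_at(round(mean(range(layer$pyramidale))))
rad_row <- round(mean(range(layer$radiatum)))
hil_ch <- ch_at(round(mean(range(layer$hilus))))
mol_ch <- ch_at(round(mean(range(layer$molecular))))

cfg <- simulation_config(
  probe = probe, sampling_rate = 10000, duration = 60, seed = seed,
  ripple_rate = 0.35, ds_rate = 0.15,
  gamma_specs = list(gamma_spec(60, 25, rows = layer$radiatum)),
  unit_specs = list(
    unit_spec(ch_at(rad_row), firing_rate = 15, kappa = 2, gamma_source = 1,
              trough_to_peak = 0.35, amplitude_length_constant = 80),
    unit_spec(pyr_ch, firing_rate = 8, trough_to_peak = 0.65,
              ripple_gain = 3, amplitude_length_constant = 80),
    unit_spec(ch_at(26), firing_rate = 6, trough_to_peak = 0.7,
              amplitude_length_constant = 80)))

message("simulating 60 s, ", nrow(probe), " channels ...")
sim <- simulate_recording(cfg)
write_recording(sim$segment, file.path(out, "recording.bin"),
                file.path(out, "recording.json"),
                extra = list(seed = seed))
write_probe_map(probe, file.path(out, "probe_map.json"))
write_ground_truth(sim$truth, json_path = file.path(out, "ground_truth.json"),
                   spikes_csv_path = file.path(out, "spikes.csv"))
meta <- list(seed = seed, pyr_channel = pyr_ch, hilus_channel = hil_ch,
             molecular_channel = mol_ch,
             n_ripples = nrow(sim$truth$ripples),
             n_ds = length(sim$truth$ds_times),
             n_units = length(sim$truth$units))
jsonlite::write_json(meta, file.path(out, "meta.json"), auto_unbox = TRUE,
                     digits = NA)
message(sprintf("ground truth: %d ripples, %d dentate spikes, %d units",
                meta$n_ripples, meta$n_ds, meta$n_units))
message("LFP-band RMS on the pyramidale channel: ",
        round(band_rms(sim$segment, pyr_ch, c(0.1, 300)), 2), " uV")
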