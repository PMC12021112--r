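# Shared synthetic fixtures, built once per test run and memoised.
# All probes here are reduced single-shank maps (full 30 um vertical pitch,
# fewer rows) so that simulations stay small; the geometry rules are
# identical to the full map.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

small_probe <- function(n_rows = 16L, n_shanks = 1L) {
  build_probe_map(n_shanks = n_shanks, n_rows = n_rows)
}

# mid-layer channel (column 0) for a named layer of a small probe
layer_channel <- function(probe, layer_name) {
  rows <- default_layer_rows(max(probe$row) + 1L)[[layer_name]]
  probe$channel_id[probe$row == round(mean(range(rows))) &
                     probe$column == 0][1]
}

# 60 s single-shank recording with 20 ripples at the default in-band SNR;
# shared by the ripple-recovery and ripple-CSD checks
fix_ripple_sim <- function() {
  fixture("ripple_sim", function() {
    probe <- small_probe(16L)
    cfg <- simulation_config(probe = probe, sampling_rate = 20000,
                             duration = 60, seed = 101,
                             ripple_times = seq(2, 58, length.out = 20))
    sim <- simulate_recording(cfg)
    list(probe = probe, sim = sim,
         pyr = layer_channel(probe, "pyramidale"))
  })
}

# short noise-free recording with one stamped unit (used by waveform checks)
fix_clean_unit_sim <- function() {
  fixture("clean_unit_sim", function() {
    probe <- small_probe(32L)
    soma <- probe$channel_id[probe$row == 16 & probe$column == 0][1]
    cfg <- simulation_config(
      probe = probe, sampling_rate = 20000, duration = 4, seed = 7,
      lfp_noise_rms = 0, ap_noise_rms = 0,
      unit_specs = list(unit_spec(soma, firing_rate = 10, slope_above = 0.5,
                                  slope_below = 0.5, trough_to_peak = 0.5,
                                  amplitude_length_constant = 100)))
    sim <- simulate_recording(cfg)
    list(probe = probe, sim = sim, soma = soma,
         fp = extract_footprint(sim$segment,
                                sim$truth$units[[1]]$spike_times,
                                unit_id = 1L))
  })
}

# synthetic footprint built directly from an exponential-decay trough model:
# troughs delayed by slope * |dy|, amplitude decaying with length constant
synthetic_footprint <- function(probe, soma_channel, slope_above = 0.5,
                                slope_below = 0.5, lambda_um = 100,
                                p2p_uv = 82, t2p_ms = 0.6, fs = 20000,
                                jitter_ms = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t_ms <- seq(-1, 2, by = 1 / fs * 1000)
  i <- match(soma_channel, probe$channel_id)
  d <- sqrt((probe$x - probe$x[i])^2 + (probe$y - probe$y[i])^2)
  rel <- exp(-d / lambda_um)
  dy_mm <- (probe$y - probe$y[i]) / 1000
  delay <- ifelse(dy_mm < 0, slope_above * abs(dy_mm), slope_below * dy_mm)
  if (jitter_ms > 0) delay <- delay + stats::rnorm(length(delay), 0, jitter_ms)
  w <- t(vapply(seq_len(nrow(probe)), function(ci) {
    rel[ci] * hippomap:::spike_template(t_ms - delay[ci], t2p_ms, p2p_uv)
  }, numeric(length(t_ms))))
  unit_footprint(w, t_ms, probe$channel_id, unit_id = 1L)
}
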