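test_that("von Mises sampler converges to the Bessel-ratio resultant", {
  # oracle: population resultant length of a von Mises sample is
  # I1(kappa)/I0(kappa)
  r <- resultant_length(spike_phases_von_mises(200000, 2, seed = 5))
  expect_lt(abs(r - besselI(2, 1) / besselI(2, 0)), 0.005)  # 0.698
  expect_lt(resultant_length(spike_phases_von_mises(50000, 0, seed = 5)), 0.02)
  ph <- spike_phases_von_mises(1000, 200, mu = 1, seed = 5)
  expect_gt(resultant_length(ph), 0.99)
  expect_lt(abs(atan2(mean(sin(ph)), mean(cos(ph))) - 1), 0.02)
  expect_error(spike_phases_von_mises(10, -1), "kappa")
})

test_that("band_rms matches closed forms", {
  fs <- 20000
  t <- (0:(4 * fs - 1)) / fs
  seg <- recording_segment(matrix(3 * sin(2 * pi * 100 * t), nrow = 1), fs)
  expect_lt(abs(band_rms(seg, 0, c(0.1, 300)) - 3 / sqrt(2)), 0.01)
  expect_lt(band_rms(seg, 0, c(300, 5000)), 0.01)
  set.seed(2)
  segn <- recording_segment(matrix(rnorm(4 * fs, sd = 5), nrow = 1), fs)
  # Parseval: full-Nyquist band RMS equals the sample SD
  expect_lt(abs(band_rms(segn, 0, c(0.1, fs / 2)) - 5) / 5, 0.02)
  expect_error(band_rms(seg, 0, c(100, 20000)), "Nyquist")
})

test_that("background noise hits the configured band RMS values", {
  probe <- build_probe_map(1L, 4L)
  lr <- list(pyramidale = 0:1, radiatum = 1:2, lacunosum = 2:2,
             molecular = 2:3, hilus = 3:3)
  sim <- simulate_recording(simulation_config(
    probe = probe, sampling_rate = 20000, duration = 8, seed = 3,
    layer_rows = lr))
  expect_lt(abs(band_rms(sim$segment, 0, c(0.1, 300)) - 16.45) / 16.45, 0.05)
  expect_lt(abs(band_rms(sim$segment, 0, c(300, 5000)) - 6.67) / 6.67, 0.05)
})

test_that("simulation is bit-identical under a fixed seed", {
  probe <- build_probe_map(1L, 8L)
  cfg <- simulation_config(probe = probe, sampling_rate = 5000, duration = 1,
                           seed = 99, ripple_rate = 0.5, ds_rate = 0.3)
  a <- simulate_recording(cfg)
  b <- simulate_recording(cfg)
  expect_identical(a$segment$data, b$segment$data)
  expect_identical(a$truth, b$truth)
})

test_that("trough-delay stamping follows the linear rule", {
  fx <- fix_clean_unit_sim()
  # channel 10 rows (300 um) below the soma, same column
  probe <- fx$probe
  soma_row <- probe$row[match(fx$soma, probe$channel_id)]
  ch_below <- probe$channel_id[probe$row == soma_row + 10 & probe$column == 0]
  tr <- detect_trough_channels(fx$fp, probe, threshold_frac = 0,
                               radius_um = 310, smooth_cutoff_hz = NULL)
  d <- tr$trough_ms[tr$channel_id == ch_below] -
    tr$trough_ms[tr$channel_id == fx$soma]
  expect_lt(abs(d - 0.5 * 0.300), 0.01)   # 0.15 ms at 0.5 ms/mm
})

test_that("waveform amplitude decays exponentially with distance", {
  fx <- fix_clean_unit_sim()
  probe <- fx$probe
  p2p <- apply(fx$fp$waveform, 1, function(w) max(w) - min(w))
  i <- match(fx$soma, probe$channel_id)
  d <- sqrt((probe$x - probe$x[i])^2 + (probe$y - probe$y[i])^2)
  on <- p2p > 2
  fit <- stats::lm(log(p2p[on]) ~ d[on])
  expect_lt(abs(-1 / coef(fit)[2] - 100) / 100, 0.1)  # length constant 100 um
})

test_that("components are additive and absence of events leaves pure noise", {
  probe <- build_probe_map(1L, 8L)
  cfg0 <- simulation_config(probe = probe, sampling_rate = 5000, duration = 2,
                            seed = 11)
  sim0 <- simulate_recording(cfg0)
  expect_equal(nrow(sim0$truth$ripples), 0)
  expect_length(sim0$truth$ds_times, 0)
  # same seed plus a gamma source: difference is exactly the sinusoid
  cfg1 <- simulation_config(probe = probe, sampling_rate = 5000, duration = 2,
                            seed = 11,
                            gamma_specs = list(gamma_spec(60, 20, rows = 2:4)))
  sim1 <- simulate_recording(cfg1)
  diffmat <- sim1$segment$data - sim0$segment$data
  on <- probe$row %in% 2:4
  expect_lt(max(abs(diffmat[!on, ])), 1e-9)
  expect_lt(abs(max(diffmat[on, ]) - 20) / 20, 0.01)
})

test_that("config validation rejects inconsistent setups", {
  probe <- build_probe_map(1L, 8L)
  expect_error(simulation_config(probe = probe, layer_rows =
    list(pyramidale = 0:1, radiatum = 1:2, lacunosum = 2:2,
         molecular = 2:3, hilus = 3:99)), "row span")
  expect_error(simulation_config(probe = probe,
    unit_specs = list(unit_spec(0, kappa = 2))), "gamma_source")
  expect_error(simulation_config(probe = probe, sampling_rate = 100,
                                 ripple_rate = 1), "Nyquist")
  expect_error(unit_spec(0, peak_amplitude = -1))
})

test_that("recording and ground truth round-trip through disk formats", {
  probe <- build_probe_map(1L, 8L)
  cfg <- simulation_config(probe = probe, sampling_rate = 5000, duration = 1,
                           seed = 4, ripple_rate = 1,
                           unit_specs = list(unit_spec(4, firing_rate = 30)))
  sim <- simulate_recording(cfg)
  d <- withr::local_tempdir()
  write_recording(sim$segment, file.path(d, "r.bin"), file.path(d, "r.json"))
  back <- read_recording(file.path(d, "r.bin"), file.path(d, "r.json"))
  expect_equal(dim(back$data), dim(sim$segment$data))
  # quantisation at 0.2 uV/bit: half-step worst case
  expect_lt(max(abs(back$data - sim$segment$data)), 0.1001)
  write_ground_truth(sim$truth, json_path = file.path(d, "gt.json"),
                     spikes_csv_path = file.path(d, "spikes.csv"))
  spk <- utils::read.csv(file.path(d, "spikes.csv"))
  expect_equal(nrow(spk), length(sim$truth$units[[1]]$spike_times))
  expect_false(is.unsorted(spk$time_s))
})
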