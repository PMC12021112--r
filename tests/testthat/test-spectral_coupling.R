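test_that("instantaneous phase tracks a pure tone at the stated rate", {
  fs <- 1000
  t <- (0:(10 * fs - 1)) / fs
  x <- 4 * sin(2 * pi * 60 * t)
  ph <- instantaneous_phase(x, fs, 60)
  mid <- (fs):(9 * fs)
  slope <- stats::coef(stats::lm(unwrap ~ t[mid],
                                 data = list(unwrap = cumsum(c(ph[mid][1],
                                   atan2(sin(diff(ph[mid])), cos(diff(ph[mid]))))))))[2]
  expect_lt(abs(slope - 2 * pi * 60) / (2 * pi * 60), 0.001)
  # amplitude invariance
  expect_equal(instantaneous_phase(10 * x, fs, 60)[mid], ph[mid],
               tolerance = 1e-9)
  # selectivity: a 200 Hz contaminant does not derail the 60 Hz phase
  x2 <- x + 4 * sin(2 * pi * 200 * t + 1)
  ph2 <- instantaneous_phase(x2, fs, 60)
  expect_lt(max(abs(atan2(sin(ph2[mid] - ph[mid]), cos(ph2[mid] - ph[mid])))),
            0.1)
  expect_error(instantaneous_phase(x, fs, 499), "Nyquist")
})

test_that("PLV has its closed-form values and bounds", {
  expect_equal(resultant_length(rep(1.2, 50)), 1)
  expect_lt(resultant_length(c(0, pi / 2, pi, 3 * pi / 2)), 1e-12)
  set.seed(4)
  for (i in 1:20) {
    r <- resultant_length(runif(sample(1:50, 1), -pi, pi))
    expect_gte(r, 0); expect_lte(r, 1)
  }
  ph <- spike_phases_von_mises(200000, 2, seed = 9)
  expect_lt(abs(resultant_length(ph) - besselI(2, 1) / besselI(2, 0)), 0.005)
  expect_error(plv(numeric(0), rep(0, 100), 1000), "spikes")
})

test_that("PLV null expectation follows the sqrt(pi/(4n)) law", {
  # Monte-Carlo against the closed form for uniform phases
  set.seed(31)
  for (n in c(50, 500)) {
    r <- replicate(400, resultant_length(runif(n, -pi, pi)))
    expect_lt(abs(mean(r) - sqrt(pi / (4 * n))) / sqrt(pi / (4 * n)), 0.1)
  }
})

test_that("PLV map localises a laminar gamma source and respects the floor", {
  probe <- build_probe_map(1L, 16L)
  rows_on <- 5:7
  cfg <- simulation_config(
    probe = probe, sampling_rate = 1250, duration = 60, seed = 12,
    ap_noise_rms = 0,
    gamma_specs = list(gamma_spec(60, 30, rows = rows_on)),
    unit_specs = list(unit_spec(6, firing_rate = 12, kappa = 3,
                                gamma_source = 1)))
  sim <- simulate_recording(cfg)
  st <- sim$truth$units[[1]]$spike_times
  pm <- plv_map(st, sim$segment, probe, freqs = seq(40, 80, by = 5))
  on <- probe$row %in% rows_on
  f60 <- which(pm$freqs == 60)
  expect_gt(min(pm$values[on, f60]), 0.5)
  # off-source rows at the source frequency stay near the null floor
  expect_lt(stats::median(pm$values[!on, f60]), 3 / sqrt(pm$n_spikes))
  # off-frequency values on source rows are low too
  expect_lt(stats::median(pm$values[on, pm$freqs == 40]),
            3 / sqrt(pm$n_spikes))
  expect_error(plv_map(st[1:50], sim$segment, probe), "spikes")
})

test_that("map smoothing averages 2x2 blocks and keeps constants fixed", {
  probe <- build_probe_map(1L, 8L)
  vals <- matrix(rep(0.25, 16 * 2), nrow = 16)
  pm <- structure(list(values = vals, freqs = c(40, 45),
                       channel_ids = probe$channel_id, n_spikes = 500,
                       smoothed = FALSE), class = "plv_map")
  sm <- smooth_plv_map(pm, probe)
  expect_equal(sm$values, vals)
  # block means: rows (2k, 2k+1) x both columns
  v2 <- matrix(seq_len(32) / 32, nrow = 16)
  pm$values <- v2
  sm2 <- smooth_plv_map(pm, probe)
  blk <- paste(probe$shank, probe$row %/% 2)
  for (b in unique(blk)) {
    expect_true(all(abs(sweep(sm2$values[blk == b, , drop = FALSE], 2,
                              colMeans(v2[blk == b, , drop = FALSE]))) < 1e-12))
  }
})

test_that("SWR interval selection caps, warns, and rejects overlap", {
  ev <- data.frame(start = 0, peak = seq(1, 300, by = 2), end = 0)
  iv <- select_swr_intervals(ev, n = 100)
  expect_equal(nrow(iv), 100)
  expect_true(all(iv$end - iv$start == 1))
  expect_warning(iv3 <- select_swr_intervals(ev[1:3, ], n = 100), "3 of 100")
  expect_equal(nrow(iv3), 3)
  ev2 <- data.frame(start = 0, peak = c(5, 5.4), end = 0)
  expect_warning(iv2 <- select_swr_intervals(ev2, n = 100), "1 of")
  expect_equal(nrow(iv2), 1)
  expect_error(select_swr_intervals(ev[0, ]), "empty")
})

test_that("coherence is 1 for self, high for shared source, low for noise", {
  fs <- 1000
  dur <- 110
  n <- dur * fs
  set.seed(18)
  shared <- band_limited_noise(n, fs, c(30, 90), 20)
  x <- rbind(shared + band_limited_noise(n, fs, c(1, 400), 2),
             shared + band_limited_noise(n, fs, c(1, 400), 2),
             band_limited_noise(n, fs, c(1, 400), 10),
             band_limited_noise(n, fs, c(1, 400), 10))
  seg <- recording_segment(x, fs)
  iv <- data.frame(start = seq(0.5, 100.5, by = 1))
  iv$end <- iv$start + 1
  iv <- iv[1:100, ]
  cm <- coherence_map(seg, 0, intervals = iv)
  expect_equal(cm$values[1], 1)                # self-coherence exactly 1
  expect_gt(cm$values[2], 0.9)                 # shared broadband source
  expect_lt(cm$values[3], 0.1)                 # independent channels
  expect_lt(cm$values[4], 0.1)
  # symmetry: swapping the roles of the pair gives the same value
  cm2 <- coherence_map(seg, 1, intervals = iv)
  expect_lt(abs(cm2$values[1] - cm$values[2]), 0.02)
  expect_error(coherence_map(seg, 0, intervals = iv[1, ]), "2 intervals")
  expect_error(coherence_map(seg, 0,
                             intervals = data.frame(start = c(0, 2),
                                                    end = c(0.3, 2.3))),
               "0.5 s")
})
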