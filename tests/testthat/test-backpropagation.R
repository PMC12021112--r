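test_that("trough search honours the amplitude threshold and radius", {
  probe <- build_probe_map(1L, 32L)
  soma <- probe$channel_id[probe$row == 16 & probe$column == 0][1]
  # length constant such that amplitude is 10% at 200 um: beyond excluded
  lam <- 200 / log(1 / 0.10)
  fp <- synthetic_footprint(probe, soma, lambda_um = lam)
  tr <- detect_trough_channels(fp, probe)
  expect_true(all(abs(tr$dy_um) <= 250))
  expect_true(all(exp(-sqrt(tr$dy_um^2) / lam) >= 0.119 |
                    tr$channel_id == soma))
  expect_false(any(abs(tr$dy_um) > 200 & tr$channel_id != soma))
  # threshold 0: every channel within the radius is returned
  tr0 <- detect_trough_channels(fp, probe, threshold_frac = 0)
  expect_equal(sort(tr0$channel_id),
               sort(channels_within_radius(probe, soma, 250)))
  # isolated unit: footprint nonzero only at the soma
  w <- matrix(0, nrow = nrow(probe), ncol = 41)
  w[match(soma, probe$channel_id), ] <-
    hippomap:::spike_template(seq(-1, 1, by = 0.05), 0.6, 82)
  fpi <- unit_footprint(w, seq(-1, 1, by = 0.05), probe$channel_id)
  tri <- detect_trough_channels(fpi, probe, smooth_cutoff_hz = NULL)
  expect_equal(tri$channel_id, soma)
})

test_that("slope fits are translation invariant and handle degeneracies", {
  tab <- data.frame(channel_id = 0:7,
                    y_um = c(400, 430, 460, 490, 520, 550, 580, 610),
                    dy_um = c(-120, -90, -60, -30, 0, 30, 60, 90),
                    trough_ms = c(.06, .045, .03, .015, 0, .018, .036, .054),
                    amplitude_uv = c(30, 40, 55, 70, 80, 68, 52, 38))
  f <- fit_backprop_slopes(tab, soma_y_um = 520)
  expect_equal(f$initiation_channel, 4)
  expect_lt(abs(f$slope_above - 0.5), 1e-9)
  expect_lt(abs(f$slope_below - 0.6), 1e-9)
  expect_equal(classify_backprop(f), "curved")
  expect_equal(f$speed_below, 1 / 0.6)
  # translation invariance
  tab2 <- tab; tab2$trough_ms <- tab$trough_ms + 0.73
  f2 <- fit_backprop_slopes(tab2, soma_y_um = 520)
  expect_equal(f2$slope_above, f$slope_above)
  expect_equal(f2$slope_below, f$slope_below)
  expect_equal(classify_backprop(f2), "curved")
  # all delays zero: slope 0 with the simultaneity flag
  tab3 <- tab; tab3$trough_ms <- 0.2
  f3 <- fit_backprop_slopes(tab3, soma_y_um = 520)
  expect_true(f3$simultaneous)
  expect_equal(f3$slope_above, 0)
  expect_equal(classify_backprop(f3), "undetermined")
  # single channel: nothing to fit
  f4 <- fit_backprop_slopes(tab[5, ], soma_y_um = 520)
  expect_equal(classify_backprop(f4), "undetermined")
  # underpopulated side: only below fitted
  f5 <- fit_backprop_slopes(tab[4:8, ], soma_y_um = 520)
  expect_true(is.na(f5$slope_above))
  expect_equal(classify_backprop(f5), "descending")
})

test_that("initiation site is the earliest trough, ties to the soma", {
  tab <- data.frame(channel_id = c(3L, 1L, 5L),
                    y_um = c(100, 130, 160),
                    dy_um = c(-30, 0, 30),
                    trough_ms = c(0.2, 0.2, 0.25),
                    amplitude_uv = c(40, 80, 40))
  f <- fit_backprop_slopes(tab, soma_y_um = 130)
  expect_equal(f$initiation_channel, 1L)  # tie at 0 delay: closest to soma
})

test_that("noise-free generator round-trip recovers slopes to 2%", {
  fx <- fix_clean_unit_sim()
  res <- backprop_analysis(fx$fp, fx$probe)
  expect_lt(abs(res$slope_above_ms_per_mm - 0.5) / 0.5, 0.02)
  expect_lt(abs(res$slope_below_ms_per_mm - 0.5) / 0.5, 0.02)
  expect_equal(res$direction, "curved")
  expect_equal(res$soma_channel, fx$soma)
})

test_that("slopes survive trough-time jitter within the stated error", {
  # Monte-Carlo oracle: additive timing jitter SD 0.05 ms over 8 equal-
  # amplitude channels leaves the regression slope within 20% typically
  set.seed(17)
  dist_um <- seq(30, 240, by = 30)
  errs <- replicate(200, {
    tab <- data.frame(channel_id = 0:8,
                      y_um = c(0, dist_um),
                      dy_um = c(0, dist_um),
                      trough_ms = c(0, dist_um / 1000) +
                        c(0, rnorm(8, 0, 0.05)),
                      amplitude_uv = 50)
    f <- fit_backprop_slopes(tab, soma_y_um = 0)
    abs(f$slope_below - 1)
  })
  expect_lt(stats::median(errs), 0.2)
})
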