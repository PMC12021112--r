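make_fp <- function(w, dt_ms = 0.05) {
  unit_footprint(matrix(w, nrow = 1), t_ms = (seq_along(w) - 1) * dt_ms,
                 channel_ids = 0L)
}

test_that("trough-to-peak latency on constructed waveforms", {
  t <- seq(0, 3, by = 0.05)
  w <- -exp(-(t - 1.0)^2 / (2 * 0.08^2)) + 0.4 * exp(-(t - 1.3)^2 / (2 * 0.15^2))
  expect_lt(abs(trough_to_peak(make_fp(w)) - 0.3), 0.02)
  # time-reversed waveform: trough at the end, no post-trough peak
  expect_error(trough_to_peak(make_fp(rev(w))), "post-trough")
  expect_error(trough_to_peak(make_fp(abs(w))), "negative trough")
})

test_that("generator round-trip recovers the configured trough-to-peak", {
  fx <- fix_clean_unit_sim()
  expect_lt(abs(trough_to_peak(fx$fp) - 0.5), 0.05)  # one sample at 20 kHz
})

test_that("classification truth table and partition property", {
  expect_equal(classify_cell_type(0.30, 2.0), "narrow_interneuron")
  expect_equal(classify_cell_type(0.50, 7.0), "wide_interneuron")
  expect_equal(classify_cell_type(0.50, 3.0), "pyramidal")
  expect_equal(classify_cell_type(0.50, NaN), "pyramidal")
  # every (t2p, rise) pair receives exactly one deterministic label
  set.seed(8)
  for (i in 1:200) {
    t2p <- runif(1, 0.1, 1.2)
    rise <- sample(c(runif(1, 0.2, 20), NaN), 1)
    lab <- classify_cell_type(t2p, rise)
    expect_true(lab %in% c("narrow_interneuron", "wide_interneuron",
                           "pyramidal"))
    if (t2p < 0.425) expect_equal(lab, "narrow_interneuron")
    else if (is.finite(rise) && rise > 6) expect_equal(lab, "wide_interneuron")
    else expect_equal(lab, "pyramidal")
  }
})

test_that("burst detection equals a brute-force ISI run scan", {
  expect_equal(detect_bursts(c(0, 5, 50) / 1000), list(1:2))
  expect_equal(detect_bursts(c(0, 20, 40) / 1000), list())
  expect_equal(detect_bursts(c(0, 5, 8, 100) / 1000), list(1:3))
  expect_error(detect_bursts(c(2, 1)), "sorted")

  brute <- function(st, thr = 0.009) {
    in_burst <- rep(FALSE, length(st))
    for (i in seq_len(length(st) - 1)) {
      if (st[i + 1] - st[i] < thr) in_burst[c(i, i + 1)] <- TRUE
    }
    sum(in_burst) / length(st)
  }
  set.seed(21)
  for (i in 1:200) {
    st <- sort(runif(sample(5:60, 1), 0, 0.5))
    expect_equal(burst_fraction(st), brute(st))
  }
})

test_that("soma localisation maximises peak-to-peak with documented ties", {
  probe <- build_probe_map(1L, 4L)
  w <- matrix(0, nrow = 8, ncol = 10)
  w[3, ] <- c(0, -5, -20, -3, 8, 12, 4, 0, 0, 0)
  w[6, ] <- w[3, ]   # exact tie: lower channel id wins
  fp <- unit_footprint(w, t_ms = 0:9 * 0.05, channel_ids = probe$channel_id)
  s <- estimate_soma_channel(fp, probe)
  expect_equal(s$channel_id, 2L)
  expect_equal(s$y_um, probe$y[probe$channel_id == 2])
  fp2 <- unit_footprint(2 * w, t_ms = 0:9 * 0.05,
                        channel_ids = probe$channel_id)
  expect_equal(estimate_soma_channel(fp2, probe)$channel_id, 2L)
  fp0 <- unit_footprint(matrix(0, 8, 10), t_ms = 0:9 * 0.05,
                        channel_ids = probe$channel_id)
  expect_error(estimate_soma_channel(fp0, probe), "all-zero")
})

test_that("generator round-trip localises the soma exactly", {
  fx <- fix_clean_unit_sim()
  expect_equal(estimate_soma_channel(fx$fp, fx$probe)$channel_id, fx$soma)
})

test_that("peri-event histogram has the stated expectations", {
  events <- c(1, 2, 3)
  # spikes exactly at events: single peak bin at lag 0 of height 1/bin
  h <- peri_event_histogram(events, events, window_ms = c(-50, 50), bin_ms = 10)
  expect_equal(h$rate_hz[h$lag_ms == 5], 0)
  expect_equal(sum(h$rate_hz > 0), 1)
  expect_equal(max(h$rate_hz), 1 / 0.010)
  # homogeneous Poisson: all bins near the rate
  set.seed(3)
  st <- cumsum(rexp(20000, 50))
  ev <- seq(10, max(st) - 10, by = 1)
  hp <- peri_event_histogram(st, ev, window_ms = c(-100, 100), bin_ms = 20)
  expect_lt(max(abs(hp$rate_hz - 50)) / 50, 0.15)
  # histogram mass: sum(rate * bin) / 1 = mean spikes per window
  lags <- unlist(lapply(ev, function(e) {
    d <- (st - e) * 1000
    d[d >= -100 & d < 100]
  }))
  expect_equal(sum(hp$rate_hz * 0.020), length(lags) / length(ev))
  expect_error(peri_event_histogram(st, numeric(0)), "zero events")
  expect_error(peri_event_histogram(st, ev, window_ms = c(-100, 100),
                                    bin_ms = 13), "tile")
})

test_that("ACG fit separates flat from slow-rising autocorrelograms", {
  set.seed(14)
  st <- cumsum(rexp(6000, 10))            # Poisson, flat ACG
  fit <- fit_acg_triple_exponential(st)
  expect_true(fit$converged)
  expect_lt(fit$tau_rise, 6)
  # fitted plateau near the firing rate
  late <- fit$acg$lag_ms >= 0.75 * max(fit$acg$lag_ms)
  expect_lt(abs(mean(fit$fitted[late]) - 10) / 10, 0.25)
  # 15 ms post-spike suppression: slow rise
  isi <- 0.015 + rexp(6000, 20)
  st2 <- cumsum(isi)
  fit2 <- fit_acg_triple_exponential(st2)
  expect_gt(fit2$tau_rise, 6)
  # determinism
  fit3 <- fit_acg_triple_exponential(st2)
  expect_identical(fit2$tau_rise, fit3$tau_rise)
  expect_error(fit_acg_triple_exponential(st[1:100]), "at least")
})

test_that("unit metrics table combines the per-unit measures", {
  fx <- fix_clean_unit_sim()
  tab <- unit_metrics_table(list(fx$fp), fx$probe, min_spikes_acg = 10000)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$soma_channel, fx$soma)
  expect_true(is.nan(tab$acg_rise_ms))     # under the spike floor
  expect_equal(tab$label, "pyramidal")     # t2p 0.5 ms, NaN rise
})
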