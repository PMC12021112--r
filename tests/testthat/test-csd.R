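test_that("a single event's triggered average is the snippet itself", {
  fs <- 1000
  set.seed(1)
  x <- matrix(rnorm(3 * fs * 2), nrow = 3)
  seg <- recording_segment(x, fs)
  avg <- event_triggered_average(seg, 1.0, window_ms = c(-50, 50))
  i0 <- round(1.0 * fs) + 1
  expect_equal(avg$data, x[, (i0 - 50):(i0 + 50)])
  expect_equal(avg$n, 1)
})

test_that("averaging suppresses noise around a repeated template", {
  fs <- 2000
  tpl <- 3 * exp(-((-100:100) / 20)^2)   # deterministic injected transient
  n <- 120 * fs / 10                  # 12 s at fs
  set.seed(2)
  x <- rnorm(12 * fs)
  events <- seq(0.5, 11.5, length.out = 100)
  for (e in events) {
    i0 <- round(e * fs) + 1
    x[(i0 - 100):(i0 + 100)] <- x[(i0 - 100):(i0 + 100)] + tpl
  }
  seg <- recording_segment(matrix(x, nrow = 1), fs)
  avg <- event_triggered_average(seg, events, window_ms = c(-50, 50))
  expect_equal(avg$n, 100)
  expect_gt(stats::cor(avg$data[1, ], tpl), 0.99)
  # equivariance: shifting events shifts the average
  avg2 <- event_triggered_average(seg, events + 0.005, window_ms = c(-50, 50))
  lag <- which.max(avg$data[1, ]) - which.max(avg2$data[1, ])
  expect_equal(lag, round(0.005 * fs))
})

test_that("out-of-range events are dropped and zero events error", {
  fs <- 1000
  seg <- recording_segment(matrix(rnorm(fs), nrow = 1), fs)
  expect_message(event_triggered_average(seg, c(0.0, 0.5), c(-100, 100)),
                 "dropped")
  expect_error(event_triggered_average(seg, c(-5, 10), c(-100, 100)),
               "no usable events")
})

test_that("CSD of a depth-linear potential vanishes at interior rows", {
  probe <- build_probe_map(1L, 16L)
  col0 <- probe[probe$column == 0, ]
  V <- matrix(rep(2 + 0.05 * col0$y, 3), ncol = 3)  # linear in depth
  avg <- triggered_average(V, lag_ms = c(-1, 0, 1), n = 5,
                           channel_ids = col0$channel_id)
  cs <- compute_csd(avg, probe, shank = 0, column = 0)
  interior <- 2:(nrow(cs$values) - 1)
  expect_lt(max(abs(cs$values[interior, ])), 1e-12)
})

test_that("a Gaussian sink profile yields a flanked negative extremum", {
  probe <- build_probe_map(1L, 32L)
  col0 <- probe[probe$column == 0, ]
  r0 <- 14
  prof <- -100 * exp(-(col0$row - r0)^2 / (2 * 3^2))
  avg <- triggered_average(matrix(prof, ncol = 1), lag_ms = 0, n = 1,
                           channel_ids = col0$channel_id)
  cs <- compute_csd(avg, probe, shank = 0, column = 0)
  v <- cs$values[, 1]
  expect_equal(cs$rows[which.min(v)], r0)      # sink at the injected row
  # sources flank the sink beyond the profile's inflection (|r - r0| > sigma)
  expect_gt(v[which.min(v) - 5], 0)
  expect_gt(v[which.min(v) + 5], 0)
  # analytic oracle: -d2V/dy2 of the Gaussian at its centre is positive
  # inside V<0, i.e. the CSD (sinks negative) is negative there
  expect_lt(min(v), 0)
  # linearity
  avg2 <- triggered_average(matrix(2 * prof, ncol = 1), lag_ms = 0, n = 1,
                            channel_ids = col0$channel_id)
  cs2 <- compute_csd(avg2, probe, shank = 0, column = 0)
  expect_equal(cs2$values, 2 * cs$values)
})

test_that("discrete dipole conservation: interior CSD sums to ~0", {
  probe <- build_probe_map(1L, 32L)
  col0 <- probe[probe$column == 0, ]
  prof <- 80 * exp(-(col0$row - 10)^2 / 8) - 80 * exp(-(col0$row - 20)^2 / 8)
  avg <- triggered_average(matrix(prof, ncol = 1), lag_ms = 0, n = 1,
                           channel_ids = col0$channel_id)
  cs <- compute_csd(avg, probe, shank = 0, column = 0)
  # compactly supported dipole: total transmembrane current balances
  expect_lt(abs(sum(cs$values)) / sum(abs(cs$values)), 0.01)
})

test_that("non-uniform pitch and short columns are rejected", {
  probe <- build_probe_map(1L, 8L)
  avg <- triggered_average(matrix(rnorm(16), ncol = 2), lag_ms = c(0, 1),
                           n = 1, channel_ids = probe$channel_id[probe$column == 0])
  bad <- probe
  bad$y[bad$column == 0][3] <- bad$y[bad$column == 0][3] + 7
  expect_error(compute_csd(avg, bad, shank = 0, column = 0), "pitch")
})

test_that("ripple-triggered CSD localises the radiatum sink", {
  fx <- fix_ripple_sim()
  ev <- detect_ripples(fx$sim$segment, fx$pyr)
  avg <- event_triggered_average(fx$sim$segment, ev$peak,
                                 window_ms = c(-100, 100))
  cs <- compute_csd(avg, fx$probe, shank = 0, column = 0)
  at0 <- cs$values[, which.min(abs(cs$lag_ms))]
  sink_row <- cs$rows[which.min(at0)]
  rad <- default_layer_rows(16L)$radiatum
  expect_true(sink_row %in% rad)
  i <- which.min(at0)
  expect_gt(at0[i - 2], 0)
  expect_gt(at0[i + 2], 0)
})
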