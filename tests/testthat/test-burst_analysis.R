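test_that("hand-traced boundary cases of the ISI rule", {
  # two sub-80 ms ISIs join, 260 ms terminates
  b <- detect_bursts(c(0, 0.07, 0.14, 0.40))
  expect_equal(nrow(b), 1)
  expect_equal(b$n_spikes, 3)
  expect_equal(b$first_spike, 1)
  expect_equal(b$last_spike, 3)

  # widely spaced spikes never burst
  expect_equal(nrow(detect_bursts(c(0, 1, 2, 3))), 0)

  # onset requires ISI strictly below 80 ms
  expect_equal(nrow(detect_bursts(c(0, 0.08, 0.16))), 0)

  # continuation tolerates ISIs up to and including 160 ms
  b <- detect_bursts(c(0, 0.07, 0.22))
  expect_equal(nrow(b), 1)
  expect_equal(b$n_spikes, 3)
  expect_true(b$truncated)  # open at the last spike
})

test_that("burst classification agrees exactly with the state-machine oracle", {
  set.seed(20240917)
  for (i in 1:1000) {
    n <- sample(10:500, 1)
    times <- random_spike_train(n)
    b <- detect_bursts(times)
    expect_identical(burst_membership(times, b), burst_oracle(times))
  }
})

test_that("bursts partition spikes into disjoint ordered index ranges", {
  set.seed(7)
  for (i in 1:50) {
    times <- random_spike_train(sample(20:200, 1))
    b <- detect_bursts(times)
    if (nrow(b) < 2) next
    expect_true(all(diff(b$first_spike) > 0))
    expect_true(all(b$first_spike[-1] > b$last_spike[-nrow(b)]))
    expect_true(all(b$n_spikes == b$last_spike - b$first_spike + 1))
  }
})

test_that("pct_swb responds monotonically to the ISI thresholds", {
  set.seed(11)
  for (i in 1:25) {
    times <- random_spike_train(150)
    n <- length(times)
    base <- percent_swb(detect_bursts(times), n)
    wider <- percent_swb(
      detect_bursts(times, burst_params(offset_isi = 0.30)), n)
    tighter <- percent_swb(
      detect_bursts(times, burst_params(onset_isi = 0.04)), n)
    expect_gte(wider, base)   # raising the offset never loses burst spikes
    expect_lte(tighter, base) # lowering the onset never gains burst spikes
  }
})

test_that("burst membership is scale-equivariant", {
  set.seed(3)
  times <- random_spike_train(120)
  b1 <- detect_bursts(times)
  for (c_scale in c(0.25, 4)) {
    b2 <- detect_bursts(times * c_scale,
                        burst_params(onset_isi = 0.080 * c_scale,
                                     offset_isi = 0.160 * c_scale))
    expect_identical(b1$first_spike, b2$first_spike)
    expect_identical(b1$last_spike, b2$last_spike)
  }
})

test_that("percent_swb arithmetic and degenerate cases", {
  b <- detect_bursts(c(0, 0.07, 0.14, 0.40))
  expect_equal(percent_swb(b, 4), 75)
  expect_equal(percent_swb(detect_bursts(c(0, 1, 2)), 3), 0)
  expect_equal(percent_swb(detect_bursts(c(0, 0.05, 0.1)), 3), 100)
  expect_true(is.na(percent_swb(b, 0)))
})

test_that("up-state amplitude recovers a planted square plateau", {
  # -60 mV baseline, one 5-s plateau at -50 mV carrying regular spikes
  t <- seq(0, 20, by = 1e-4)
  v <- rep(-60, length(t))
  v[t >= 7.5 & t <= 12.5] <- -50
  spikes <- seq(7.6, 12.4, by = 0.07)  # ~14 Hz, all inside the plateau
  sigma <- 1e-3
  for (s in spikes) {
    win <- abs(t - s) < 4 * sigma
    v[win] <- v[win] + 70 * exp(-(t[win] - s)^2 / (2 * sigma^2))
  }
  tr <- voltage_trace(t, v)
  bursts <- detect_bursts(spikes)
  expect_equal(nrow(bursts), 1)
  ups <- up_state_amplitude(tr, spikes, bursts)
  expect_lt(abs(ups$delta_mv - 10), 0.2)

  # constant trace with no bursts: delta undefined
  flat <- voltage_trace(t, rep(-60, length(t)))
  ups0 <- up_state_amplitude(flat, numeric(0), detect_bursts(numeric(0)))
  expect_true(is.na(ups0$delta_mv))
  expect_equal(ups0$down_state_mv, -60)
})

test_that("up-state pools in-burst samples across plateaus (median)", {
  t <- seq(0, 30, by = 1e-3)
  v <- rep(-60, length(t))
  v[t >= 5 & t < 10] <- -52    # +8 mV plateau
  v[t >= 20 & t < 25] <- -48   # +12 mV plateau
  tr <- voltage_trace(t, v)
  bursts <- data.frame(first_spike = c(1L, 3L), last_spike = c(2L, 4L),
                       n_spikes = c(2L, 2L), start_s = c(5, 20),
                       end_s = c(10 - 1e-3, 25 - 1e-3),
                       duration_s = c(5, 5) - 1e-3,
                       intraburst_freq_hz = c(1, 1), truncated = FALSE)
  ups <- up_state_amplitude(tr, numeric(0), bursts)
  expect_equal(ups$delta_mv, 10, tolerance = 1e-6)
})

test_that("burst_summary averages burst descriptors", {
  b <- detect_bursts(c(0, 0.07, 0.14, 0.40))
  s <- burst_summary(b)
  expect_equal(s$n_bursts, 1)
  expect_equal(s$mean_intraburst_freq_hz, 2 / 0.14, tolerance = 1e-9)

  s0 <- burst_summary(detect_bursts(c(0, 1, 2)))
  expect_equal(s0$n_bursts, 0)
  expect_true(is.na(s0$mean_duration_s))

  # planted intra-burst ISI of 1/11.6 s across 100 bursts is recovered
  set.seed(5)
  trains <- lapply(1:100, function(i) {
    n <- sample(30:60, 1)
    cumsum(c(0, pmin(stats::rgamma(n - 1, shape = 16, scale = (1 / 11.6) / 16),
                     0.155)))
  })
  offs <- cumsum(rep(30, 100))
  times <- unlist(mapply(`+`, trains, offs, SIMPLIFY = FALSE))
  b <- detect_bursts(times)
  expect_equal(nrow(b), 100)
  expect_lt(abs(burst_summary(b)$mean_intraburst_freq_hz - 11.6) / 11.6, 0.02)
})
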