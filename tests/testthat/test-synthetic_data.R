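test_that("the simulator is deterministic for a fixed seed", {
  a <- simulate_trace(preset_config("nas", seed = 42, duration_s = 20))
  b <- simulate_trace(preset_config("nas", seed = 42, duration_s = 20))
  expect_identical(a$trace$voltage, b$trace$voltage)
  expect_identical(a$truth$spike_times, b$truth$spike_times)
  c1 <- simulate_trace(preset_config("nas", seed = 43, duration_s = 20))
  expect_false(identical(a$trace$voltage, c1$trace$voltage))
})

test_that("bursty mode with no interburst singles has fraction exactly 1", {
  cfg <- preset_config("ast", seed = 8, duration_s = 60, pause_rate_hz = 0,
                       interburst_pause_s = 10, interburst_pause_sd_s = 2,
                       interburst_pause_range_s = c(5, 20))
  x <- simulate_trace(cfg)
  expect_gt(length(x$truth$spike_times), 0)
  expect_identical(x$truth$in_burst_spike_fraction, 1)
})

test_that("full pipeline recovers planted truth on noise-free traces", {
  for (seed in c(1, 2, 3)) {
    for (pre in c("nas", "ast")) {
      x <- simulate_trace(preset_config(pre, seed = seed, noise_sd_mv = 0))
      sp <- detect_spikes(x$trace)
      expect_identical(length(sp$spike_times), length(x$truth$spike_times))
      expect_true(all(abs(sp$spike_times - x$truth$spike_times) <
                        1.5 / x$truth$config$sampling_rate))
      b <- detect_bursts(sp)
      swb <- percent_swb(b, length(sp$spike_times))
      expect_lt(abs(swb - 100 * x$truth$in_burst_spike_fraction), 2)
      # burst boundaries within one intra-burst ISI of the planted intervals
      if (nrow(x$truth$burst_intervals) && nrow(b)) {
        tol <- 0.165  # one continuation ISI (<= 160 ms) plus a sample
        for (k in seq_len(nrow(x$truth$burst_intervals))) {
          tb <- x$truth$burst_intervals[k, ]
          hit <- which(abs(b$start_s - tb$start_s) < tol &
                         abs(b$end_s - tb$end_s) < tol)
          expect_length(hit, 1)
        }
      }
    }
  }
})

test_that("planted plateau amplitudes are recovered under noise", {
  for (plateau in c(5.91, 10.54, 14.13)) {
    cfg <- preset_config("ast", seed = 17, plateau_mv = plateau,
                         noise_sd_mv = 0.5)
    x <- simulate_trace(cfg)
    sp <- detect_spikes(x$trace)
    b <- detect_bursts(sp)
    ups <- up_state_amplitude(x$trace, sp, b)
    expect_lt(abs(ups$delta_mv - plateau), 0.5)
  }
})

test_that("NAS-like and AST-like presets produce the planted %SWB contrast", {
  nas <- simulate_trace(preset_config("nas", seed = 31))
  ast <- simulate_trace(preset_config("ast", seed = 31))
  swb <- function(x) {
    sp <- detect_spikes(x$trace)
    percent_swb(detect_bursts(sp), length(sp$spike_times))
  }
  expect_gt(swb(ast) - swb(nas), 40)
})

test_that("overlapping spike templates are rejected", {
  cfg <- preset_config("nas", seed = 1, duration_s = 10,
                       pacemaker_rate_hz = 300, pacemaker_cv = 0,
                       spike_half_width_ms = 8)
  expect_error(simulate_trace(cfg), "template wider")
})

test_that("evoked-current generator matches its closed form", {
  cu <- simulate_evoked_current(150, rise_tau_s = 0.1, decay_tau_s = 1,
                                noise_sd_pa = 0, seed = 1)
  expect_lt(abs(min(cu$current) + 150) / 150, 0.01)
  expect_true(all(cu$current[cu$time < 10] == 0))

  flat <- simulate_evoked_current(0, noise_sd_pa = 0, seed = 1)
  expect_true(all(flat$current == 0))

  # same-seed determinism
  n1 <- simulate_evoked_current(100, noise_sd_pa = 2, seed = 9)
  n2 <- simulate_evoked_current(100, noise_sd_pa = 2, seed = 9)
  expect_identical(n1$current, n2$current)
})

test_that("2:1 evoked-current amplitudes separate in the binned KS test", {
  big <- simulate_evoked_current(200, rise_tau_s = 0.5, decay_tau_s = 20,
                                 onset_s = 5, duration_s = 30,
                                 noise_sd_pa = 2, seed = 11)
  small <- simulate_evoked_current(100, rise_tau_s = 0.5, decay_tau_s = 20,
                                   onset_s = 5, duration_s = 30,
                                   noise_sd_pa = 2, seed = 12)
  r <- ks_compare(bin_timecourse(big, 1), bin_timecourse(small, 1))
  expect_gt(r$D, 0.5)
  expect_lt(r$p, 0.05)
})

test_that("sniffer generator plants recoverable per-stimulus release", {
  fl <- simulate_sniffer(per_stim_dff = 0.5, noise_sd = 1, seed = 21)
  d <- dff(fl)
  amps <- vapply(fl$stim_times, function(ts) {
    pre <- d$dff[max(which(d$time < ts))]
    peak <- max(d$dff[d$time >= ts & d$time < ts + 0.2])
    peak - pre
  }, 0)
  expect_lt(abs(mean(amps) - 0.5) / 0.5, 0.05)

  quiet <- dff(simulate_sniffer(per_stim_dff = 0, noise_sd = 0, seed = 1))
  expect_true(all(abs(quiet$dff - 1) < 1e-12))
})
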