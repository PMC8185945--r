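test_that("flat trace yields an empty spike train; planted spikes are found", {
  t <- seq(0, 1, by = 1e-4)
  flat <- voltage_trace(t, rep(-60, length(t)))
  st <- detect_spikes(flat)
  expect_s3_class(st, "spike_train")
  expect_length(st$spike_times, 0)

  planted <- c(0.1, 0.25, 0.4, 0.62, 0.8)
  tr <- gaussian_spike_trace(planted, amp_mv = 70, fwhm_ms = 2,
                             duration_s = 1)
  st <- detect_spikes(tr)
  expect_length(st$spike_times, 5)
  expect_true(all(abs(st$spike_times - planted) <= 1e-4 + 1e-12))
})

test_that("detection count is noise-robust at sigma = 0.5 mV", {
  planted <- c(0.1, 0.25, 0.4, 0.62, 0.8)
  tr <- gaussian_spike_trace(planted, amp_mv = 70, fwhm_ms = 2,
                             duration_s = 1, noise_sd = 0.5, seed = 1)
  st <- detect_spikes(tr)
  expect_length(st$spike_times, 5)
})

test_that("noise-free detection has unit sensitivity and no false positives", {
  for (seed in 1:100) {
    set.seed(seed)
    n <- sample(5:15, 1)
    planted <- sort(stats::runif(n, 0.05, 4.95))
    planted <- planted[c(TRUE, diff(planted) > 0.02)]  # keep templates apart
    tr <- gaussian_spike_trace(planted, amp_mv = 60 + runif(1, 0, 30),
                               fwhm_ms = runif(1, 1.5, 3), duration_s = 5)
    st <- detect_spikes(tr)
    expect_length(st$spike_times, length(planted))
  }
})

test_that("detected peak jitter stays within one sample under noise", {
  for (seed in 1:10) {
    planted <- seq(0.1, 1.9, by = 0.2)
    tr <- gaussian_spike_trace(planted, amp_mv = 75, fwhm_ms = 1.5,
                               duration_s = 2, noise_sd = 0.5, seed = seed)
    st <- detect_spikes(tr)
    expect_length(st$spike_times, length(planted))
    expect_true(all(abs(st$spike_times - planted) <= 1e-4 + 1e-12))
  }
})

test_that("Gaussian template half-width matches the closed-form FWHM", {
  # FWHM of A*exp(-t^2 / (2 sigma^2)) measured from its baseline is
  # 2*sigma*sqrt(2 log 2) = 2.355 ms for sigma = 1 ms
  sigma_ms <- 1
  fwhm_ms <- 2 * sigma_ms * sqrt(2 * log(2))
  tr <- gaussian_spike_trace(0.5, amp_mv = 70, fwhm_ms = fwhm_ms,
                             duration_s = 1)
  f <- extract_features(tr, 0.5, threshold_mv = -60)
  expect_lt(abs(f$half_width_ms - fwhm_ms), 0.1)  # one sample period
  expect_equal(f$amplitude, 70, tolerance = 1e-6)
  expect_false(f$edge_truncated)
})

test_that("triangular spike of 2 ms base has a 1 ms half-width", {
  t <- seq(0, 0.2, by = 1e-4)
  v <- rep(-60, length(t))
  apex <- 0.1
  ramp <- abs(t - apex) <= 1e-3
  v[ramp] <- -60 + 40 * (1 - abs(t[ramp] - apex) / 1e-3)
  tr <- voltage_trace(t, v)
  f <- extract_features(tr, apex, threshold_mv = -60)
  expect_equal(f$half_width_ms, 1, tolerance = 1e-6)
})

test_that("spike at the trace edge is flagged edge-truncated", {
  t <- seq(0, 0.1, by = 1e-4)
  sigma <- 1e-3
  v <- -60 + 70 * exp(-(t - 0.1)^2 / (2 * sigma^2))  # peak on last sample
  tr <- voltage_trace(t, v)
  f <- extract_features(tr, 0.1, threshold_mv = -60)
  expect_true(f$edge_truncated)
})

test_that("half-width is invariant under time reversal for symmetric spikes", {
  tr <- gaussian_spike_trace(c(0.3, 0.7), amp_mv = 70, fwhm_ms = 2.5,
                             duration_s = 1)
  rev_tr <- voltage_trace(tr$time, rev(tr$voltage))
  f1 <- extract_features(tr, c(0.3, 0.7), threshold_mv = -60)
  f2 <- extract_features(rev_tr, 1 - c(0.7, 0.3), threshold_mv = -60)
  expect_equal(f1$half_width_ms, f2$half_width_ms, tolerance = 1e-9)
})

test_that("phase portrait of a sinusoid reaches 2*pi*f*A within 0.5%", {
  f_hz <- 5; amp_mv <- 10
  t <- seq(0, 1, by = 1e-4)
  tr <- voltage_trace(t, amp_mv * sin(2 * pi * f_hz * t))
  pp <- phase_portrait(tr)
  expected <- 2 * pi * f_hz * amp_mv / 1000  # V/s
  expect_lt(abs(max(abs(pp$dvdt)) - expected) / expected, 0.005)

  const <- voltage_trace(t, rep(-60, length(t)))
  expect_true(all(phase_portrait(const)$dvdt == 0))
  expect_error(phase_portrait(tr, smooth_points = length(t)), "smooth_points")
})

test_that("narrower spike templates produce larger max dV/dt", {
  narrow <- gaussian_spike_trace(0.5, amp_mv = 75, fwhm_ms = 2.12,
                                 duration_s = 1)
  wide <- gaussian_spike_trace(0.5, amp_mv = 75, fwhm_ms = 3.11,
                               duration_s = 1)
  expect_gt(max(phase_portrait(narrow)$dvdt), max(phase_portrait(wide)$dvdt))
})

test_that("neuron inclusion criteria follow the -35 mV / 60 mV rule", {
  # healthy: resting -60 mV, amplitude ~70 mV
  tr <- gaussian_spike_trace(seq(0.2, 1.8, by = 0.4), amp_mv = 70,
                             fwhm_ms = 2, baseline_mv = -60, duration_s = 2)
  qc <- qc_neuron(tr, detect_spikes(tr))
  expect_true(qc$pass)
  expect_lt(abs(qc$resting_potential + 60), 0.5)
  expect_gt(qc$mean_amplitude, 60)

  # depolarized resting potential fails the resting criterion
  tr2 <- gaussian_spike_trace(seq(0.2, 1.8, by = 0.4), amp_mv = 70,
                              fwhm_ms = 2, baseline_mv = -30, duration_s = 2)
  qc2 <- qc_neuron(tr2, detect_spikes(tr2))
  expect_false(qc2$pass)
  expect_true("resting_potential" %in% qc2$reasons)

  # small spikes fail the amplitude criterion
  tr3 <- gaussian_spike_trace(seq(0.2, 1.8, by = 0.4), amp_mv = 55,
                              fwhm_ms = 2, baseline_mv = -60, duration_s = 2)
  qc3 <- qc_neuron(tr3, detect_spikes(tr3, min_peak = -20))
  expect_false(qc3$pass)
  expect_identical(qc3$reasons, "amplitude")
})
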