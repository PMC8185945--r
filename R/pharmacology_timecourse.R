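#' Extract a sub-trace for an analysis window
#'
#' @param trace a [voltage_trace()].
#' @param window `c(start_s, end_s)`, inclusive, within the trace span.
#' @return A `voltage_trace` restricted to the window.
#' @keywords internal
subset_trace <- function(trace, window) {
  keep <- trace$time >= window[1] & trace$time <= window[2]
  if (sum(keep) < 2) stop("window contains fewer than 2 samples")
  voltage_trace(trace$time[keep], trace$voltage[keep],
                neuron_id = trace$neuron_id, group = trace$group)
}

# metric row from precomputed per-window pieces
window_metrics <- function(sub, spikes, bursts, window, blank_ms = 5) {
  fs <- firing_summary(spikes, window)
  ups <- up_state_amplitude(sub, spikes, bursts, blank_ms = blank_ms)
  ok <- spikes$features[!spikes$features$edge_truncated, , drop = FALSE]
  data.frame(
    mean_rate_hz = fs$mean_rate_hz,
    pct_swb = percent_swb(bursts, length(spikes$spike_times)),
    up_state_delta_mv = ups$delta_mv,
    cv_isi_pct = fs$cv_isi_pct,
    half_width_ms = if (nrow(ok)) mean(ok$half_width_ms) else NA_real_,
    amplitude_mv = if (nrow(ok)) mean(ok$amplitude) else NA_real_,
    n_spikes = fs$n_spikes,
    n_bursts = nrow(bursts))
}

# full per-window firing analysis shared by compare_epochs and run_pipeline
analyze_window <- function(trace, window, dvdt_threshold = 10, min_peak = -10,
                           refractory_ms = 2, params = burst_params(),
                           blank_ms = 5) {
  sub <- subset_trace(trace, window)
  spikes <- detect_spikes(sub, dvdt_threshold = dvdt_threshold,
                          min_peak = min_peak, refractory_ms = refractory_ms)
  bursts <- detect_bursts(spikes, params)
  window_metrics(sub, spikes, bursts, window, blank_ms = blank_ms)
}

#' Baseline-versus-drug epoch comparison for one neuron
#'
#' Runs the identical firing analysis (spike detection, burst
#' classification, rate/CV summaries, up-state estimate, waveform features)
#' on a baseline window and a drug window and tabulates the paired metrics.
#' By default the baseline is the 60 s ending at drug onset and the drug
#' window is the 60 s starting `drug_delay_s` (default 420 s, i.e. 7 min)
#' after onset, matching the convention of averaging 1-min intervals at
#' baseline and after 7-10 min of drug.
#'
#' @param trace a [voltage_trace()] spanning both windows.
#' @param drug_onset_s drug application time, seconds.
#' @param baseline_window_s duration of each analysis window, seconds.
#' @param drug_delay_s gap between onset and the start of the drug window.
#' @param baseline_window,drug_window optional explicit `c(start_s, end_s)`
#'   windows overriding the defaults.
#' @param ... analysis parameters forwarded to the per-window analysis
#'   (`dvdt_threshold`, `min_peak`, `refractory_ms`, `params`, `blank_ms`).
#' @return list of class `epoch_comparison`: `neuron_id`, `metrics`
#'   (data.frame `metric`, `baseline`, `drug`), `baseline_window`,
#'   `drug_window`.
#' @export
compare_epochs <- function(trace, drug_onset_s, baseline_window_s = 60,
                           drug_delay_s = 420,
                           baseline_window = NULL, drug_window = NULL, ...) {
  stopifnot(inherits(trace, "voltage_trace"))
  span <- range(trace$time)
  if (is.null(baseline_window))
    baseline_window <- c(drug_onset_s - baseline_window_s, drug_onset_s)
  if (is.null(drug_window))
    drug_window <- drug_onset_s + drug_delay_s + c(0, baseline_window_s)
  wins <- list(baseline = baseline_window, drug = drug_window)
  for (nm in names(wins)) {
    w <- wins[[nm]]
    if (w[1] < span[1] - 1e-9 || w[2] > span[2] + 1e-9)
      stop(sprintf("%s window [%.6g, %.6g] outside trace span [%.6g, %.6g]",
                   nm, w[1], w[2], span[1], span[2]))
  }
  base <- analyze_window(trace, baseline_window, ...)
  drug <- analyze_window(trace, drug_window, ...)
  metrics <- data.frame(metric = names(base),
                        baseline = as.numeric(base[1, ]),
                        drug = as.numeric(drug[1, ]))
  structure(list(neuron_id = trace$neuron_id, metrics = metrics,
                 baseline_window = baseline_window, drug_window = drug_window),
            class = "epoch_comparison")
}

#' @export
print.epoch_comparison <- function(x, ...) {
  cat(sprintf("<epoch_comparison> %s: baseline [%.6g, %.6g] vs drug [%.6g, %.6g]\n",
              x$neuron_id, x$baseline_window[1], x$baseline_window[2],
              x$drug_window[1], x$drug_window[2]))
  print(x$metrics)
  invisible(x)
}

#' Bin a time series into contiguous fixed-width means
#'
#' Averages the signal over contiguous bins (1 s by default, the
#' conventional resolution for evoked-current time courses); a trailing
#' partial bin is dropped.
#'
#' @param trace a [current_trace()], [fluorescence_trace()] or [dff()]
#'   result.
#' @param bin_width_s bin width, seconds (> 0).
#' @return list of class `binned_timecourse`: `bin_centers` (s),
#'   `bin_means`, `bin_width_s`.
#' @export
bin_timecourse <- function(trace, bin_width_s = 1) {
  stopifnot(bin_width_s > 0)
  value <- if (inherits(trace, "current_trace")) trace$current
           else if (inherits(trace, "fluorescence_trace")) trace$intensity
           else if (inherits(trace, "dff_trace")) trace$dff
           else stop("trace must be a current, fluorescence or dff trace")
  t <- trace$time
  dt <- (t[length(t)] - t[1]) / (length(t) - 1)
  n_bins <- floor(length(t) * dt / bin_width_s + 1e-9)
  if (n_bins < 1) stop("bin wider than the trace")
  idx <- floor((t - t[1]) / bin_width_s + 1e-9)
  keep <- idx < n_bins
  means <- as.numeric(tapply(value[keep], idx[keep], mean))
  structure(list(bin_centers = t[1] + (seq_len(n_bins) - 0.5) * bin_width_s,
                 bin_means = means, bin_width_s = bin_width_s),
            class = "binned_timecourse")
}

#' Two-sample Kolmogorov-Smirnov comparison of binned time courses
#'
#' Compares the distributions of bin means of two time courses (the
#' convention for deciding whether two evoked-current or release time
#' courses differ) with the two-sample KS test, asymptotic p value.
#'
#' @param a,b [bin_timecourse()] results, or numeric vectors.
#' @return list with `D` (sup of the pooled-ECDF difference, in \[0, 1\]),
#'   `p`.
#' @export
ks_compare <- function(a, b) {
  x <- if (inherits(a, "binned_timecourse")) a$bin_means else as.numeric(a)
  y <- if (inherits(b, "binned_timecourse")) b$bin_means else as.numeric(b)
  if (length(x) == 0 || length(y) == 0) stop("empty input to ks_compare")
  kt <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  list(D = unname(kt$statistic), p = unname(kt$p.value))
}

#' Normalize a fluorescence trace to its baseline (delta-F over F0)
#'
#' F0 is the mean intensity over the first `f0_window_s` seconds of the
#' recording; the primary output is the fold change F/F0 (a constant trace
#' sits at 1).  The relative change (F - F0)/F0 is exported alongside.
#'
#' @param trace a [fluorescence_trace()] spanning at least `f0_window_s`.
#' @param f0_window_s baseline duration, seconds.
#' @return list of class `dff_trace`: `time` (s), `dff` (fold change F/F0),
#'   `dff_delta` ((F - F0)/F0), `f0`, `stim_times`.
#' @export
dff <- function(trace, f0_window_s = 60) {
  stopifnot(inherits(trace, "fluorescence_trace"))
  t0 <- trace$time[1]
  span <- trace$time[length(trace$time)] - t0
  if (span < f0_window_s)
    stop("trace shorter than the F0 baseline window")
  f0 <- mean(trace$intensity[trace$time < t0 + f0_window_s])
  if (f0 <= 0) stop("non-positive F0: background over-subtraction")
  structure(list(time = trace$time, dff = trace$intensity / f0,
                 dff_delta = trace$intensity / f0 - 1, f0 = f0,
                 stim_times = trace$stim_times),
            class = "dff_trace")
}
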