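#' Detect action potentials by derivative threshold
#'
#' Finds spikes as upward crossings of a dV/dt threshold followed by a
#' voltage peak.  Each spike is anchored at its voltage peak; the action
#' potential threshold is taken as the voltage at the last upward crossing of
#' the dV/dt criterion before the peak, which makes amplitude
#' (peak - threshold) and half-width at half-maximal voltage well defined.
#' Candidate peaks closer together than the refractory period are merged,
#' keeping the higher peak.
#'
#' The defaults (10 V/s onset criterion, -10 mV minimum absolute peak, 2 ms
#' refractory) suit somatic current-clamp recordings of spontaneously firing
#' dopamine neurons; pacemaker spikes rise at tens of V/s so the criterion
#' sits far above channel noise yet below any spike upstroke.
#'
#' @param trace a [voltage_trace()].
#' @param dvdt_threshold onset criterion in V/s (> 0).
#' @param min_peak minimum absolute peak voltage in mV.
#' @param refractory_ms minimum separation between spikes, ms.
#' @param feature_window_ms half-window around each peak used for waveform
#'   features, ms.
#' @param peak_lookahead_ms how far past a dV/dt crossing to search for the
#'   voltage peak, ms; must exceed the rise time from the onset criterion to
#'   the peak.
#' @return An object of class `spike_train`: list with `spike_times` (s,
#'   strictly increasing), `features` (data.frame from [extract_features()]),
#'   `neuron_id`, `group`.  Zero detected spikes is a valid empty result.
#' @seealso [extract_features()], [detect_bursts()]
#' @export
detect_spikes <- function(trace, dvdt_threshold = 10, min_peak = -10,
                          refractory_ms = 2, feature_window_ms = 8,
                          peak_lookahead_ms = 5) {
  stopifnot(inherits(trace, "voltage_trace"), dvdt_threshold > 0)
  v <- trace$voltage
  n <- length(v)
  if (n < 3) stop("trace too short for derivative-based detection")
  dt <- 1 / trace$sampling_rate
  dvdt <- compute_dvdt(v, dt)

  above <- dvdt >= dvdt_threshold
  # upward crossings of the dV/dt criterion
  cross <- which(above & !c(FALSE, above[-n]))
  if (length(cross) == 0) return(empty_spike_train(trace))
  # peak = voltage argmax within a short lookahead after the crossing; noise
  # can plant spurious local maxima on the upstroke, so a plain
  # "next local max" would anchor below the real peak
  look <- max(1L, round(peak_lookahead_ms / 1000 / dt))
  peaks <- vapply(cross, function(ck) {
    hi <- min(n, ck + look)
    ck + which.max(v[ck:hi]) - 1L
  }, integer(1))
  peaks <- unique(peaks)
  peaks <- peaks[v[peaks] >= min_peak]
  if (length(peaks) == 0) return(empty_spike_train(trace))

  # refractory merge: keep the higher of two peaks closer than the refractory
  refr <- refractory_ms / 1000
  peaks <- sort(peaks)
  merged <- peaks[1]
  for (p in peaks[-1]) {
    last <- merged[length(merged)]
    if ((p - last) * dt < refr) {
      if (v[p] > v[last]) merged[length(merged)] <- p
    } else merged <- c(merged, p)
  }

  times <- trace$time[merged]
  feats <- extract_features(trace, times, window_ms = feature_window_ms,
                            dvdt_threshold = dvdt_threshold)
  structure(list(spike_times = times, features = feats,
                 neuron_id = trace$neuron_id, group = trace$group),
            class = "spike_train")
}

empty_spike_train <- function(trace) {
  structure(list(spike_times = numeric(0),
                 features = empty_features(),
                 neuron_id = trace$neuron_id, group = trace$group),
            class = "spike_train")
}

empty_features <- function() {
  data.frame(peak_time = numeric(0), peak_voltage = numeric(0),
             threshold_voltage = numeric(0), amplitude = numeric(0),
             half_width_ms = numeric(0), max_dvdt = numeric(0),
             edge_truncated = logical(0))
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %s (%s): %d spikes\n", x$neuron_id,
              ifelse(is.na(x$group), "-", x$group), length(x$spike_times)))
  invisible(x)
}

# central-difference derivative in V/s (voltage in mV, dt in s)
compute_dvdt <- function(v, dt) {
  n <- length(v)
  d <- numeric(n)
  d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * dt)
  d[1] <- (v[2] - v[1]) / dt
  d[n] <- (v[n] - v[n - 1]) / dt
  d / 1000
}

#' Per-spike waveform features
#'
#' For each spike, measures the action-potential threshold (voltage at the
#' last upward dV/dt-criterion crossing before the peak, unless an explicit
#' threshold level is supplied), amplitude (peak minus threshold), maximal
#' dV/dt, and the half-width: the time between the two crossings of the
#' half-maximal level (threshold + amplitude/2), linearly interpolated
#' between samples.  Spikes whose measurement window is clipped by the trace
#' edge, or whose half-level crossings cannot be found inside the window, are
#' flagged `edge_truncated` and should be excluded from summaries.
#'
#' @param trace the [voltage_trace()] the spikes were detected on.
#' @param spike_times spike peak times, seconds.
#' @param window_ms half-window around each peak searched for the threshold
#'   crossing and the half-level crossings, ms.
#' @param dvdt_threshold V/s, the onset criterion defining the threshold
#'   voltage (ignored when `threshold_mv` is given).
#' @param threshold_mv optional explicit threshold level(s), mV: a scalar or
#'   one value per spike.  Useful when the reference level is known, e.g. a
#'   template baseline.
#' @return data.frame with one row per spike: `peak_time`, `peak_voltage`,
#'   `threshold_voltage`, `amplitude` (mV), `half_width_ms`, `max_dvdt`
#'   (V/s), `edge_truncated`.
#' @export
extract_features <- function(trace, spike_times, window_ms = 8,
                             dvdt_threshold = 10, threshold_mv = NULL) {
  stopifnot(inherits(trace, "voltage_trace"))
  if (length(spike_times) == 0) return(empty_features())
  v <- trace$voltage
  t <- trace$time
  n <- length(v)
  dt <- 1 / trace$sampling_rate
  dvdt <- compute_dvdt(v, dt)
  w <- max(1L, round(window_ms / 1000 / dt))
  if (!is.null(threshold_mv))
    threshold_mv <- rep_len(threshold_mv, length(spike_times))

  rows <- lapply(seq_along(spike_times), function(k) {
    pk <- which.min(abs(t - spike_times[k]))
    lo <- pk - w; hi <- pk + w
    truncated <- lo < 1 || hi > n
    lo <- max(1L, lo); hi <- min(n, hi)

    if (is.null(threshold_mv)) {
      seg <- lo:pk
      up <- which(dvdt[seg] >= dvdt_threshold &
                  c(FALSE, dvdt[seg][-length(seg)] < dvdt_threshold))
      thr_idx <- if (length(up)) seg[up[length(up)]] else NA_integer_
      thr <- if (is.na(thr_idx)) NA_real_ else v[thr_idx]
    } else thr <- threshold_mv[k]

    amp <- v[pk] - thr
    hw <- NA_real_
    if (!is.na(thr) && !is.na(amp) && amp > 0) {
      half <- thr + amp / 2
      hw <- half_width_at(v, t, pk, half, lo, hi)
      if (is.na(hw)) truncated <- TRUE
    } else truncated <- TRUE

    data.frame(peak_time = t[pk], peak_voltage = v[pk],
               threshold_voltage = thr, amplitude = amp,
               half_width_ms = hw, max_dvdt = max(dvdt[lo:hi]),
               edge_truncated = truncated)
  })
  do.call(rbind, rows)
}

# width (ms) between the interpolated half-level crossings flanking sample pk;
# NA when either crossing falls outside [lo, hi]
half_width_at <- function(v, t, pk, half, lo, hi) {
  i <- pk
  while (i > lo && v[i - 1] > half) i <- i - 1
  if (i == lo) return(NA_real_)
  t_rise <- t[i - 1] + (half - v[i - 1]) / (v[i] - v[i - 1]) * (t[i] - t[i - 1])
  j <- pk
  while (j < hi && v[j + 1] > half) j <- j + 1
  if (j == hi) return(NA_real_)
  t_fall <- t[j] + (half - v[j]) / (v[j + 1] - v[j]) * (t[j + 1] - t[j])
  (t_fall - t_rise) * 1000
}

#' Phase-plane portrait of a voltage trace
#'
#' Pairs the membrane potential with its time derivative so action-potential
#' onset dynamics can be compared across cells: narrow fast-onset spikes
#' trace wider loops (larger max dV/dt) than slow smooth-onset spikes.
#'
#' @param trace a [voltage_trace()].
#' @param smooth_points optional moving-average width (samples) applied to
#'   the voltage before differentiation; 0 or 1 disables smoothing (the
#'   default, for bit-reproducibility).
#' @return An object of class `phase_portrait`: list with `voltage` (mV) and
#'   `dvdt` (V/s), paired samples of equal length.
#' @export
phase_portrait <- function(trace, smooth_points = 0) {
  stopifnot(inherits(trace, "voltage_trace"))
  v <- trace$voltage
  if (smooth_points >= length(v))
    stop("smooth_points must be smaller than the trace length")
  if (smooth_points > 1) {
    k <- rep(1 / smooth_points, smooth_points)
    sm <- as.numeric(stats::filter(v, k, sides = 2))
    keep <- !is.na(sm)
    v <- sm[keep]
  }
  d <- compute_dvdt(v, 1 / trace$sampling_rate)
  structure(list(voltage = v, dvdt = d), class = "phase_portrait")
}

#' @export
print.phase_portrait <- function(x, ...) {
  cat(sprintf("<phase_portrait> %d samples, max |dV/dt| %.4g V/s\n",
              length(x$voltage), max(abs(x$dvdt))))
  invisible(x)
}

#' Neuron inclusion criteria
#'
#' Applies the standard quality-control rule for current-clamp recordings of
#' spontaneously active neurons: the cell is accepted when its resting
#' membrane potential is below -35 mV and its mean action-potential peak
#' amplitude (peak voltage minus resting potential) exceeds 60 mV.
#'
#' The resting potential is estimated as the mode of the subthreshold voltage
#' distribution (0.5 mV bins) with spikes blanked +/- 5 ms, which is robust
#' in bursting traces where the mean is pulled up by depolarized plateaus.
#'
#' @param trace a [voltage_trace()].
#' @param spikes the [detect_spikes()] result for the same trace.
#' @return list of class `qc_result`: `resting_potential` (mV),
#'   `mean_amplitude` (mV, peak-to-resting; NA when there are no spikes),
#'   `pass` (logical), `reasons` (character vector of failed criteria, empty
#'   when passing).
#' @export
qc_neuron <- function(trace, spikes) {
  stopifnot(inherits(trace, "voltage_trace"), inherits(spikes, "spike_train"))
  sub <- blank_spikes(trace$voltage, trace$time, spikes$spike_times,
                      blank_ms = 5, bridge = FALSE)
  rmp <- voltage_mode(sub)
  amp <- if (length(spikes$spike_times))
    mean(spikes$features$peak_voltage) - rmp else NA_real_
  reasons <- character(0)
  if (!(rmp < -35)) reasons <- c(reasons, "resting_potential")
  if (is.na(amp) || !(amp > 60)) reasons <- c(reasons, "amplitude")
  structure(list(resting_potential = rmp, mean_amplitude = amp,
                 pass = length(reasons) == 0, reasons = reasons),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf("<qc_result> RMP %.2f mV, mean amplitude %s mV -> %s%s\n",
              x$resting_potential,
              ifelse(is.na(x$mean_amplitude), "NA", sprintf("%.2f", x$mean_amplitude)),
              ifelse(x$pass, "PASS", "FAIL"),
              ifelse(length(x$reasons), paste0(" (", paste(x$reasons, collapse = ", "), ")"), "")))
  invisible(x)
}

# histogram mode with fixed 0.5 mV bins; midpoint of the fullest bin
voltage_mode <- function(v, bin_mv = 0.5) {
  v <- v[!is.na(v)]
  b <- floor(v / bin_mv)
  tb <- table(b)
  (as.numeric(names(tb))[which.max(tb)] + 0.5) * bin_mv
}

# remove (bridge = FALSE -> NA) or linearly bridge samples within +/- blank_ms
# of each spike time
blank_spikes <- function(v, t, spike_times, blank_ms = 5, bridge = TRUE) {
  if (length(spike_times) == 0) return(v)
  dt <- t[2] - t[1]
  w <- round(blank_ms / 1000 / dt)
  n <- length(v)
  mask <- rep(FALSE, n)
  idx <- round((spike_times - t[1]) / dt) + 1
  for (i in idx) {
    lo <- max(1L, i - w); hi <- min(n, i + w)
    mask[lo:hi] <- TRUE
  }
  out <- v
  if (!bridge) {
    out[mask] <- NA_real_
    return(out)
  }
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (k in which(r$values)) {
    lo <- starts[k]; hi <- ends[k]
    vl <- if (lo > 1) v[lo - 1] else v[hi + 1]
    vr <- if (hi < n) v[hi + 1] else v[lo - 1]
    out[lo:hi] <- seq(vl, vr, length.out = hi - lo + 3)[2:(hi - lo + 2)]
  }
  out
}
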