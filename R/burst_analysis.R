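#' Burst-classification parameters
#'
#' The interspike-interval rule of Grace and Bunney as commonly applied to
#' dopamine neurons: a burst opens at two consecutive spikes with an ISI
#' strictly below `onset_isi` (80 ms) and terminates at the first ISI
#' strictly above `offset_isi` (160 ms); intermediate ISIs up to and
#' including `offset_isi` keep the burst going.
#'
#' @param onset_isi seconds; a pair with ISI < `onset_isi` opens a burst.
#' @param offset_isi seconds; an ISI > `offset_isi` closes the burst.
#' @param min_spikes minimum spikes per burst (the onset pair itself gives 2).
#' @return list of class `burst_params`.
#' @export
burst_params <- function(onset_isi = 0.080, offset_isi = 0.160, min_spikes = 2) {
  stopifnot(onset_isi > 0, onset_isi <= offset_isi, min_spikes >= 2)
  structure(list(onset_isi = onset_isi, offset_isi = offset_isi,
                 min_spikes = min_spikes), class = "burst_params")
}

#' Classify spikes into bursts by the interspike-interval rule
#'
#' Scans the spike train left to right.  A burst opens at the first spike of
#' a pair whose ISI is strictly less than `params$onset_isi`; subsequent
#' spikes join while the ISI stays at or below `params$offset_isi`; the
#' burst closes before the first ISI strictly above `params$offset_isi`.
#' Bursts cannot overlap by construction.  A burst still open at the last
#' spike is closed there and flagged `truncated`.
#'
#' @param spikes a [detect_spikes()] result, or a numeric vector of spike
#'   times in seconds (strictly increasing).
#' @param params a [burst_params()].
#' @return data.frame with one row per burst: `first_spike`, `last_spike`
#'   (1-based indices into the spike train), `n_spikes`, `start_s`, `end_s`,
#'   `duration_s`, `intraburst_freq_hz` ((n-1)/duration), `truncated`.
#'   Fewer than two spikes give zero rows.
#' @export
detect_bursts <- function(spikes, params = burst_params()) {
  st <- spike_times_of(spikes)
  stopifnot(inherits(params, "burst_params"))
  n <- length(st)
  empty <- data.frame(first_spike = integer(0), last_spike = integer(0),
                      n_spikes = integer(0), start_s = numeric(0),
                      end_s = numeric(0), duration_s = numeric(0),
                      intraburst_freq_hz = numeric(0), truncated = logical(0))
  if (n < 2) return(empty)
  if (any(diff(st) <= 0)) stop("spike times must be strictly increasing")
  isi <- diff(st)
  out <- list()
  i <- 1L
  while (i < n) {
    if (isi[i] < params$onset_isi) {
      j <- i + 1L
      while (j < n && isi[j] <= params$offset_isi) j <- j + 1L
      if (j - i + 1L >= params$min_spikes) {
        out[[length(out) + 1L]] <- data.frame(
          first_spike = i, last_spike = j, n_spikes = j - i + 1L,
          start_s = st[i], end_s = st[j], duration_s = st[j] - st[i],
          intraburst_freq_hz = (j - i) / (st[j] - st[i]),
          truncated = (j == n))
      }
      i <- j + 1L
    } else i <- i + 1L
  }
  if (length(out) == 0) return(empty)
  do.call(rbind, out)
}

spike_times_of <- function(spikes) {
  if (inherits(spikes, "spike_train")) spikes$spike_times
  else as.numeric(spikes)
}

#' Percentage of spikes within bursts (%SWB)
#'
#' The number of spikes falling inside any detected burst, expressed
#' relative to the total number of spikes from the same neuron.
#'
#' @param bursts data.frame from [detect_bursts()].
#' @param total_spikes total spike count of the neuron.
#' @return percent in \[0, 100\]; `NA` when `total_spikes` is 0.
#' @export
percent_swb <- function(bursts, total_spikes) {
  if (total_spikes == 0) return(NA_real_)
  100 * sum(bursts$n_spikes) / total_spikes
}

#' Up-state amplitude: depolarization during bursts
#'
#' The up-state is the membrane potential during a firing burst, depolarized
#' relative to the quiescent down-state between bursts.  Spikes are blanked
#' (+/- `blank_ms`, linear bridge) so the estimate reflects the underlying
#' plateau, not spike waveforms; the up- and down-state levels are the
#' medians of the blanked voltage inside and outside all burst intervals,
#' and the quantity reported as "up-state" is their difference in mV.
#'
#' @param trace the [voltage_trace()].
#' @param spikes the [detect_spikes()] result for the trace.
#' @param bursts data.frame from [detect_bursts()].
#' @param blank_ms half-width of the spike blanking window, ms.
#' @return list with `up_state_mv`, `down_state_mv`, `delta_mv` (up minus
#'   down).  With no bursts `up_state_mv` and `delta_mv` are NA; with bursts
#'   covering the whole trace `down_state_mv` and `delta_mv` are NA.
#' @export
up_state_amplitude <- function(trace, spikes, bursts, blank_ms = 5) {
  stopifnot(inherits(trace, "voltage_trace"))
  st <- spike_times_of(spikes)
  v <- blank_spikes(trace$voltage, trace$time, st, blank_ms = blank_ms,
                    bridge = TRUE)
  if (nrow(bursts) == 0) {
    return(list(up_state_mv = NA_real_,
                down_state_mv = stats::median(v), delta_mv = NA_real_))
  }
  inb <- rep(FALSE, length(v))
  for (k in seq_len(nrow(bursts))) {
    inb[trace$time >= bursts$start_s[k] & trace$time <= bursts$end_s[k]] <- TRUE
  }
  up <- stats::median(v[inb])
  down <- if (all(inb)) NA_real_ else stats::median(v[!inb])
  list(up_state_mv = up, down_state_mv = down, delta_mv = up - down)
}

#' Summary statistics over detected bursts
#'
#' @param bursts data.frame from [detect_bursts()].
#' @return one-row data.frame: `n_bursts`, `mean_n_spikes`,
#'   `mean_duration_s`, `mean_intraburst_freq_hz` (NA when no bursts).
#' @export
burst_summary <- function(bursts) {
  if (nrow(bursts) == 0) {
    return(data.frame(n_bursts = 0L, mean_n_spikes = NA_real_,
                      mean_duration_s = NA_real_,
                      mean_intraburst_freq_hz = NA_real_))
  }
  data.frame(n_bursts = nrow(bursts),
             mean_n_spikes = mean(bursts$n_spikes),
             mean_duration_s = mean(bursts$duration_s),
             mean_intraburst_freq_hz = mean(bursts$intraburst_freq_hz))
}
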