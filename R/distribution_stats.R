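#' Interspike-interval distribution of one neuron
#'
#' ISIs between adjacent spikes inside the analysis window, their
#' instantaneous frequencies (1/ISI), and the empirical cumulative
#' distribution used for per-neuron cumulative-probability curves.  Curves
#' are per neuron and never pooled across neurons; group-level aggregation
#' happens on scalar summaries only.
#'
#' @param spikes a [detect_spikes()] result or numeric spike times (s).
#' @param window `c(start_s, end_s)`; only spikes inside are used.  Defaults
#'   to the full span of the spike train.
#' @return list of class `isi_distribution`: `isis` (s), `inst_freq` (Hz),
#'   `ecdf` (data.frame `value`, `prob`: step function at the sorted ISIs,
#'   ending exactly at 1), `median_isi` (s, the 50%-probability value),
#'   `n_spikes`, `insufficient` (TRUE when fewer than 2 spikes fall in the
#'   window, in which case the distribution is empty).
#' @export
isi_distribution <- function(spikes, window = NULL) {
  st <- spike_times_of(spikes)
  if (is.null(window)) window <- range(st, na.rm = TRUE)
  st <- st[st >= window[1] & st <= window[2]]
  if (length(st) < 2) {
    return(structure(list(isis = numeric(0), inst_freq = numeric(0),
                          ecdf = data.frame(value = numeric(0), prob = numeric(0)),
                          median_isi = NA_real_, n_spikes = length(st),
                          insufficient = TRUE),
                     class = "isi_distribution"))
  }
  isis <- diff(st)
  s <- sort(isis)
  ec <- data.frame(value = unique(s),
                   prob = cumsum(tabulate(match(s, unique(s)))) / length(s))
  structure(list(isis = isis, inst_freq = 1 / isis, ecdf = ec,
                 median_isi = stats::median(isis), n_spikes = length(st),
                 insufficient = FALSE),
            class = "isi_distribution")
}

#' @export
print.isi_distribution <- function(x, ...) {
  cat(sprintf("<isi_distribution> %d spikes, median ISI %s s\n", x$n_spikes,
              ifelse(is.na(x$median_isi), "NA", sprintf("%.4g", x$median_isi))))
  invisible(x)
}

#' Firing-rate and regularity summary of one neuron
#'
#' Mean firing rate (spike count over the window duration) and the
#' coefficient of variation of the ISI, computed as the sample standard
#' deviation divided by the mean, times 100%.  ISIs are conventionally taken
#' over 1 min of spontaneous activity; the window is configurable.
#'
#' @param spikes a [detect_spikes()] result or numeric spike times (s).
#' @param window `c(start_s, end_s)` with positive duration.
#' @return one-row data.frame: `mean_rate_hz`, `cv_isi_pct` (NA with fewer
#'   than 3 spikes), `median_isi_s`, `median_inst_freq_hz`, `n_spikes`.
#' @export
firing_summary <- function(spikes, window) {
  st <- spike_times_of(spikes)
  stopifnot(length(window) == 2, diff(window) > 0)
  st <- st[st >= window[1] & st <= window[2]]
  n <- length(st)
  isis <- if (n >= 2) diff(st) else numeric(0)
  cv <- if (n >= 3) 100 * stats::sd(isis) / mean(isis) else NA_real_
  data.frame(mean_rate_hz = n / diff(window),
             cv_isi_pct = cv,
             median_isi_s = if (n >= 2) stats::median(isis) else NA_real_,
             median_inst_freq_hz = if (n >= 2) stats::median(1 / isis) else NA_real_,
             n_spikes = n)
}
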