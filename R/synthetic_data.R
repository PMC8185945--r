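#' Simulation configuration for synthetic membrane-potential traces
#'
#' The generator is phenomenological: spikes are rendered from a stereotyped
#' template on top of a two-state (down/up) baseline, with every planted
#' event recorded exactly, so the analysis pipeline can be validated against
#' known ground truth.  Two firing modes are supported:
#'
#' * `"pacemaker"` - slow quasi-regular single spiking (Gamma-distributed
#'   ISIs) with an optional fraction of events replaced by small bursts of a
#'   few spikes riding a modest depolarization; emulates healthy
#'   dopamine-neuron firing at 1-4 Hz with occasional 3-8 spike bursts.
#' * `"bursty"` - a semi-Markov alternation of long depolarized plateaus
#'   (up-states) carrying high-frequency spiking and quiescent pauses with
#'   sparse single spikes; emulates the prolonged broadbrimmed-burst
#'   phenotype (intra-burst 5-25 Hz, tens to hundreds of spikes, 5-25 s
#'   plateaus).
#'
#' Up/down state durations are truncated-normal draws; intra-burst and
#' pacemaker ISIs are Gamma draws whose CV is directly configurable.  ISI
#' draws are floored at the spike-template support so templates never
#' overlap.
#'
#' @param mode `"pacemaker"` or `"bursty"`.
#' @param duration_s,sampling_rate trace length (s) and rate (Hz).
#' @param baseline_mv down-state membrane potential, mV.
#' @param pacemaker_rate_hz,pacemaker_cv event rate (Hz) and ISI coefficient
#'   of variation of the pacemaker process.
#' @param small_burst_prob probability a pacemaker event is a small burst.
#' @param small_burst_size inclusive `c(min, max)` spikes per small burst.
#' @param small_burst_rate_hz intra-burst rate of small bursts, Hz.
#' @param small_burst_plateau_mv depolarization under a small burst, mV.
#' @param burst_rate_hz,burst_rate_cv intra-burst firing rate (Hz) and ISI CV
#'   in bursty mode.
#' @param burst_duration_s,burst_duration_sd_s,burst_duration_range_s
#'   truncated-normal up-state duration (mean, sd, bounds), seconds.
#' @param interburst_pause_s,interburst_pause_sd_s,interburst_pause_range_s
#'   truncated-normal pause duration (mean, sd, bounds), seconds.
#' @param pause_rate_hz rate of sparse single spikes during pauses (Poisson).
#' @param plateau_mv up-state depolarization above baseline, mV.
#' @param ramp_ms cosine ramp at plateau edges, ms.
#' @param spike_amplitude_mv,spike_half_width_ms Gaussian spike template:
#'   peak height above the local baseline and full width at half maximum.
#' @param noise_sd_mv additive Gaussian noise, mV.
#' @param seed integer RNG seed; a fixed seed makes the trace bit-identical.
#' @param regime_switch optional `list(at_s =, config =)`: from `at_s`
#'   onwards spikes are generated under `config` (a `sim_config` or a named
#'   list of overrides of this one), emulating a drug that changes the
#'   firing regime.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(mode = c("pacemaker", "bursty"),
                       duration_s = 120, sampling_rate = 10000,
                       baseline_mv = -60,
                       pacemaker_rate_hz = 2, pacemaker_cv = 0.35,
                       small_burst_prob = 0, small_burst_size = c(3, 8),
                       small_burst_rate_hz = 15, small_burst_plateau_mv = 6,
                       burst_rate_hz = 11.6, burst_rate_cv = 0.25,
                       burst_duration_s = 11.2, burst_duration_sd_s = 1.5,
                       burst_duration_range_s = c(5, 25),
                       interburst_pause_s = 40, interburst_pause_sd_s = 8,
                       interburst_pause_range_s = c(10, 80),
                       pause_rate_hz = 0.2,
                       plateau_mv = 14.13, ramp_ms = 10,
                       spike_amplitude_mv = 75, spike_half_width_ms = 2.5,
                       noise_sd_mv = 0.5, seed = 1, regime_switch = NULL) {
  mode <- match.arg(mode)
  cfg <- as.list(environment())
  stopifnot(duration_s > 0, sampling_rate > 0, pacemaker_rate_hz > 0,
            small_burst_rate_hz > 0, burst_rate_hz > 0, noise_sd_mv >= 0)
  if (!is.null(regime_switch)) {
    stopifnot(is.list(regime_switch), !is.null(regime_switch$at_s))
    if (!inherits(regime_switch$config, "sim_config")) {
      base <- cfg; base$regime_switch <- NULL
      over <- regime_switch$config
      cfg$regime_switch$config <- do.call(
        sim_config, utils::modifyList(base, as.list(over)))
    }
  }
  structure(cfg, class = "sim_config")
}

#' Preset configurations for the four study groups
#'
#' Anchored to the published group phenotypes: human control ("nas",
#' pacemaker ~1 Hz, ~29% of spikes in small bursts over a ~5.9 mV
#' depolarization, half-width ~3.1 ms), human alpha-synuclein triplication
#' ("ast", broadbrimmed bursts at 11.6 Hz lasting ~11.2 s on a 14.13 mV
#' plateau, half-width ~2.1 ms), wild-type mouse ("wt-mouse") and
#' alpha-synuclein-overexpressing mouse ("asyn-oe") with the corresponding
#' mouse anchors (4.88 / 10.54 mV plateaus).  Interburst pause lengths are
#' not pinned down by published values and are chosen to reproduce the
#' qualitative long-pause phenotype at plausible overall firing rates.
#'
#' Two drug-application scenarios are included for epoch-comparison studies,
#' both 300-s recordings with the bath change at 150 s: "ast-quinpirole"
#' switches the bursty regime to a pacemaker regime anchored to the reported
#' agonist effect (rate ~1.8 Hz, about half the spikes in small bursts over a
#' 5.4 mV depolarization, spike shape unchanged), and "ast-sulpiride" keeps
#' every parameter unchanged across the switch (the antagonist's null effect
#' on rate and burstiness).
#'
#' @param preset one of "nas", "ast", "wt-mouse", "asyn-oe",
#'   "ast-quinpirole", "ast-sulpiride".
#' @param ... overrides forwarded to [sim_config()] (e.g. `seed`,
#'   `duration_s`).
#' @return A [sim_config()].
#' @export
preset_config <- function(preset = c("nas", "ast", "wt-mouse", "asyn-oe",
                                     "ast-quinpirole", "ast-sulpiride"), ...) {
  preset <- match.arg(preset)
  if (preset %in% c("ast-quinpirole", "ast-sulpiride")) {
    switch_cfg <- if (preset == "ast-quinpirole") {
      list(mode = "pacemaker", pacemaker_rate_hz = 1.08, pacemaker_cv = 0.35,
           small_burst_prob = 0.149, small_burst_rate_hz = 15,
           small_burst_plateau_mv = 5.4)
    } else list()
    return(preset_config("ast", duration_s = 300,
                         regime_switch = list(at_s = 150, config = switch_cfg),
                         ...))
  }
  base <- switch(preset,
    "nas" = list(mode = "pacemaker", pacemaker_rate_hz = 0.8,
                 pacemaker_cv = 0.35, small_burst_prob = 0.07,
                 small_burst_size = c(3, 8), small_burst_rate_hz = 15,
                 small_burst_plateau_mv = 5.91,
                 spike_amplitude_mv = 70, spike_half_width_ms = 3.11),
    "ast" = list(mode = "bursty", burst_rate_hz = 11.6, burst_rate_cv = 0.25,
                 burst_duration_s = 11.2, burst_duration_sd_s = 1.5,
                 burst_duration_range_s = c(5, 25),
                 interburst_pause_s = 40, interburst_pause_sd_s = 8,
                 interburst_pause_range_s = c(10, 80), pause_rate_hz = 0.2,
                 plateau_mv = 14.13,
                 spike_amplitude_mv = 78, spike_half_width_ms = 2.12),
    "wt-mouse" = list(mode = "pacemaker", pacemaker_rate_hz = 0.87,
                      pacemaker_cv = 0.3, small_burst_prob = 0.045,
                      small_burst_size = c(3, 8), small_burst_rate_hz = 15,
                      small_burst_plateau_mv = 4.88,
                      spike_amplitude_mv = 72, spike_half_width_ms = 2.8),
    "asyn-oe" = list(mode = "bursty", burst_rate_hz = 10, burst_rate_cv = 0.25,
                     burst_duration_s = 8, burst_duration_sd_s = 2,
                     burst_duration_range_s = c(4, 15),
                     interburst_pause_s = 30, interburst_pause_sd_s = 6,
                     interburst_pause_range_s = c(10, 60), pause_rate_hz = 0.6,
                     plateau_mv = 10.54,
                     spike_amplitude_mv = 74, spike_half_width_ms = 2.2))
  do.call(sim_config, utils::modifyList(base, list(...)))
}

rtruncnorm1 <- function(mean, sd, range) {
  if (sd <= 0) return(min(max(mean, range[1]), range[2]))
  repeat {
    x <- stats::rnorm(1, mean, sd)
    if (x >= range[1] && x <= range[2]) return(x)
  }
}

# Gamma ISI with given mean and CV, floored at min_isi; draws above max_isi
# are rejected and redrawn (used to keep intra-burst ISIs consistent with the
# planted burst membership)
r_isi <- function(n, mean, cv, min_isi, max_isi = Inf) {
  if (cv <= 0) return(rep(min(max(mean, min_isi), max_isi), n))
  shape <- 1 / cv^2
  x <- stats::rgamma(n, shape = shape, scale = mean / shape)
  for (k in 1:100) {
    bad <- x > max_isi
    if (!any(bad)) break
    x[bad] <- stats::rgamma(sum(bad), shape = shape, scale = mean / shape)
  }
  pmax(pmin(x, max_isi), min_isi)
}

# ISI rule constants the planted bursts are kept consistent with: a burst
# opens below the onset ISI and never contains an ISI above the offset ISI
BURST_ONSET_ISI <- 0.080
BURST_OFFSET_ISI <- 0.160

# event schedule for one regime over [t0, t1): spike times, per-spike burst
# membership, burst spike intervals and plateau intervals
gen_schedule <- function(cfg, t0, t1, min_isi) {
  spikes <- numeric(0); in_burst <- logical(0)
  bursts <- list(); plateaus <- list()
  if (cfg$mode == "pacemaker") {
    t <- t0 + r_isi(1, 1 / cfg$pacemaker_rate_hz, cfg$pacemaker_cv, min_isi)
    while (t < t1) {
      if (stats::runif(1) < cfg$small_burst_prob) {
        nsp <- sample(cfg$small_burst_size[1]:cfg$small_burst_size[2], 1)
        isis <- c(r_isi(1, 1 / cfg$small_burst_rate_hz, 0.15, min_isi,
                        BURST_ONSET_ISI),
                  if (nsp > 2) r_isi(nsp - 2, 1 / cfg$small_burst_rate_hz,
                                     0.15, min_isi, BURST_OFFSET_ISI))
        bs <- t + cumsum(c(0, isis))
        bs <- bs[bs < t1]
        if (length(bs) >= 2) {
          spikes <- c(spikes, bs); in_burst <- c(in_burst, rep(TRUE, length(bs)))
          bursts[[length(bursts) + 1]] <- c(bs[1], bs[length(bs)])
          plateaus[[length(plateaus) + 1]] <-
            c(bs[1] - 2 * cfg$ramp_ms / 1000, bs[length(bs)] + 2 * cfg$ramp_ms / 1000,
              cfg$small_burst_plateau_mv)
          t <- bs[length(bs)]
        } else if (length(bs) == 1) {
          spikes <- c(spikes, bs); in_burst <- c(in_burst, FALSE); t <- bs
        }
      } else {
        spikes <- c(spikes, t); in_burst <- c(in_burst, FALSE)
      }
      t <- t + r_isi(1, 1 / cfg$pacemaker_rate_hz, cfg$pacemaker_cv, min_isi)
    }
  } else {
    t <- t0
    state_up <- FALSE  # begin in a pause
    while (t < t1) {
      if (state_up) {
        dur <- rtruncnorm1(cfg$burst_duration_s, cfg$burst_duration_sd_s,
                           cfg$burst_duration_range_s)
        up_end <- min(t + dur, t1)
        nmax <- ceiling(dur * cfg$burst_rate_hz * 2) + 2
        first <- t + 2 * cfg$ramp_ms / 1000 +
          r_isi(1, 1 / cfg$burst_rate_hz, cfg$burst_rate_cv, min_isi)
        bt <- first +
          cumsum(c(0, r_isi(1, 1 / cfg$burst_rate_hz, cfg$burst_rate_cv,
                            min_isi, BURST_ONSET_ISI),
                   r_isi(nmax - 2, 1 / cfg$burst_rate_hz, cfg$burst_rate_cv,
                         min_isi, BURST_OFFSET_ISI)))
        bt <- bt[bt < up_end]
        if (length(bt) >= 2) {
          spikes <- c(spikes, bt); in_burst <- c(in_burst, rep(TRUE, length(bt)))
          bursts[[length(bursts) + 1]] <- c(bt[1], bt[length(bt)])
          plateaus[[length(plateaus) + 1]] <- c(t, up_end, cfg$plateau_mv)
        } else if (length(bt) == 1) {
          spikes <- c(spikes, bt); in_burst <- c(in_burst, FALSE)
        }
        t <- up_end
      } else {
        dur <- rtruncnorm1(cfg$interburst_pause_s, cfg$interburst_pause_sd_s,
                           cfg$interburst_pause_range_s)
        p_end <- min(t + dur, t1)
        if (cfg$pause_rate_hz > 0) {
          ts <- t + cumsum(r_isi(ceiling(dur * cfg$pause_rate_hz * 3) + 2,
                                 1 / cfg$pause_rate_hz, 1, min_isi))
          ts <- ts[ts < p_end - min_isi]
          spikes <- c(spikes, ts); in_burst <- c(in_burst, rep(FALSE, length(ts)))
        }
        t <- p_end
      }
      state_up <- !state_up
    }
  }
  list(spikes = spikes, in_burst = in_burst, bursts = bursts,
       plateaus = plateaus)
}

#' Simulate a membrane-voltage trace with planted ground truth
#'
#' Renders the firing schedule described by `config` (see [sim_config()])
#' into a uniformly sampled voltage trace: square depolarized plateaus with
#' cosine-smoothed edges, Gaussian spike templates snapped to the sample
#' grid, and additive Gaussian noise.  Every planted spike, burst interval
#' and plateau amplitude is returned, so detection, burst classification and
#' up-state estimates can be checked exactly.
#'
#' @param config a [sim_config()].
#' @return list with `trace` (a [voltage_trace()]) and `truth`, a list of
#'   class `synthetic_ground_truth`: `spike_times` (s, at sample positions),
#'   `in_burst` (logical per spike), `burst_intervals` (data.frame
#'   `start_s`, `end_s`, `n_spikes`), `plateaus` (data.frame `start_s`,
#'   `end_s`, `amplitude_mv`), `in_burst_spike_fraction`, `config`.
#' @export
simulate_trace <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  dt <- 1 / config$sampling_rate

  segs <- if (is.null(config$regime_switch)) {
    list(list(cfg = config, t0 = 0, t1 = config$duration_s))
  } else {
    sw <- config$regime_switch
    list(list(cfg = config, t0 = 0, t1 = sw$at_s),
         list(cfg = sw$config, t0 = sw$at_s, t1 = config$duration_s))
  }

  # ISI floor: templates must never overlap (8 sigma of the widest template)
  tpl_sigma <- function(cfg) cfg$spike_half_width_ms / 1000 / (2 * sqrt(2 * log(2)))
  min_isi <- max(vapply(segs, function(s) 8 * tpl_sigma(s$cfg), 0)) + 2 * dt
  for (s in segs) {
    cfg <- s$cfg
    req_isi <- if (cfg$mode == "pacemaker") {
      min(1 / cfg$pacemaker_rate_hz,
          if (cfg$small_burst_prob > 0) 1 / cfg$small_burst_rate_hz else Inf)
    } else 1 / cfg$burst_rate_hz
    if (req_isi < min_isi)
      stop("spike template wider than the minimum interspike interval")
  }

  spikes <- numeric(0); in_burst <- logical(0)
  bursts <- list(); plateaus <- list(); seg_of_spike <- integer(0)
  for (k in seq_along(segs)) {
    s <- segs[[k]]
    sch <- gen_schedule(s$cfg, s$t0, s$t1, min_isi)
    spikes <- c(spikes, sch$spikes)
    in_burst <- c(in_burst, sch$in_burst)
    seg_of_spike <- c(seg_of_spike, rep(k, length(sch$spikes)))
    bursts <- c(bursts, sch$bursts)
    plateaus <- c(plateaus, sch$plateaus)
  }

  n <- round(config$duration_s / dt) + 1L
  time <- (seq_len(n) - 1L) * dt
  # snap spikes to the sample grid so the planted peak sits on a sample
  idx <- round(spikes / dt) + 1L
  keep <- idx >= 1L & idx <= n
  idx <- idx[keep]; in_burst <- in_burst[keep]; seg_of_spike <- seg_of_spike[keep]
  spikes <- time[idx]
  # grid snapping can shorten a floored ISI by up to one sample
  if (length(idx) > 1 && any(diff(idx) * dt < min_isi - 1.5 * dt))
    stop("spike template wider than the minimum interspike interval")

  v <- rep(config$baseline_mv, n)
  ramp_s <- config$ramp_ms / 1000
  for (p in plateaus) {
    a <- p[1]; b <- p[2]; amp <- p[3]
    if (amp == 0 || b <= a) next
    i0 <- max(1L, floor(a / dt) + 1L); i1 <- min(n, ceiling(b / dt) + 1L)
    tt <- time[i0:i1]
    prof <- rep(1, length(tt))
    r1 <- tt < a + ramp_s
    prof[r1] <- 0.5 * (1 - cos(pi * (tt[r1] - a) / ramp_s))
    r2 <- tt > b - ramp_s
    prof[r2] <- pmin(prof[r2], 0.5 * (1 - cos(pi * (b - tt[r2]) / ramp_s)))
    v[i0:i1] <- v[i0:i1] + amp * pmax(prof, 0)
  }

  for (k in seq_along(segs)) {
    cfg <- segs[[k]]$cfg
    sg <- cfg$spike_half_width_ms / 1000 / (2 * sqrt(2 * log(2)))
    half_w <- round(4 * sg / dt)
    tpl <- cfg$spike_amplitude_mv * exp(-((-half_w:half_w) * dt)^2 / (2 * sg^2))
    for (i in idx[seg_of_spike == k]) {
      lo <- max(1L, i - half_w); hi <- min(n, i + half_w)
      v[lo:hi] <- v[lo:hi] + tpl[(lo - i + half_w + 1L):(hi - i + half_w + 1L)]
    }
  }

  if (config$noise_sd_mv > 0)
    v <- v + stats::rnorm(n, 0, config$noise_sd_mv)

  bi <- if (length(bursts)) {
    data.frame(start_s = vapply(bursts, `[`, 0, 1),
               end_s = vapply(bursts, `[`, 0, 2))
  } else data.frame(start_s = numeric(0), end_s = numeric(0))
  bi$n_spikes <- vapply(seq_len(nrow(bi)), function(j)
    sum(spikes >= bi$start_s[j] - dt & spikes <= bi$end_s[j] + dt & in_burst),
    0L)
  pl <- if (length(plateaus)) {
    data.frame(start_s = vapply(plateaus, `[`, 0, 1),
               end_s = vapply(plateaus, `[`, 0, 2),
               amplitude_mv = vapply(plateaus, `[`, 0, 3))
  } else data.frame(start_s = numeric(0), end_s = numeric(0),
                    amplitude_mv = numeric(0))

  truth <- structure(list(
    spike_times = spikes, in_burst = in_burst, burst_intervals = bi,
    plateaus = pl,
    in_burst_spike_fraction = if (length(spikes)) mean(in_burst) else NA_real_,
    config = config), class = "synthetic_ground_truth")
  list(trace = voltage_trace(time, v,
                             neuron_id = paste0("sim", config$seed),
                             group = config$mode),
       truth = truth)
}

#' @export
print.synthetic_ground_truth <- function(x, ...) {
  cat(sprintf("<synthetic_ground_truth> %d spikes, %d bursts, in-burst fraction %.3f\n",
              length(x$spike_times), nrow(x$burst_intervals),
              x$in_burst_spike_fraction))
  invisible(x)
}

#' Simulate an agonist-evoked inward current
#'
#' Double-exponential inward transient (rise and decay time constants) with
#' additive Gaussian noise, normalized so the planted peak equals
#' `amplitude_pa` exactly; emulates the focal-application D2R/GIRK current
#' recorded under voltage clamp at -60 mV.
#'
#' @param amplitude_pa peak inward amplitude, pA (deflection is negative).
#' @param rise_tau_s,decay_tau_s time constants, s (`decay_tau_s` >
#'   `rise_tau_s`).
#' @param onset_s application time, s.
#' @param noise_sd_pa Gaussian noise SD, pA.
#' @param duration_s,sampling_rate trace length (s) and rate (Hz).
#' @param holding_potential clamp potential, mV.
#' @param seed RNG seed.
#' @return A [current_trace()].
#' @export
simulate_evoked_current <- function(amplitude_pa, rise_tau_s = 0.1,
                                    decay_tau_s = 1, onset_s = 10,
                                    noise_sd_pa = 1, duration_s = 60,
                                    sampling_rate = 2000,
                                    holding_potential = -60, seed = 1) {
  stopifnot(rise_tau_s > 0, decay_tau_s > rise_tau_s)
  set.seed(seed)
  dt <- 1 / sampling_rate
  time <- seq(0, duration_s, by = dt)
  s <- pmax(time - onset_s, 0)
  kern <- exp(-s / decay_tau_s) - exp(-s / rise_tau_s)
  kern[time < onset_s] <- 0
  tp <- rise_tau_s * decay_tau_s / (decay_tau_s - rise_tau_s) *
    log(decay_tau_s / rise_tau_s)
  kmax <- exp(-tp / decay_tau_s) - exp(-tp / rise_tau_s)
  cur <- -amplitude_pa * kern / kmax
  if (noise_sd_pa > 0) cur <- cur + stats::rnorm(length(time), 0, noise_sd_pa)
  current_trace(time, cur, holding_potential = holding_potential,
                application_onset_s = onset_s)
}

#' Simulate a sniffer-cell fluorescence recording
#'
#' Baseline intensity `f0` with stimulus-locked exponential transients of
#' fractional amplitude `per_stim_dff` (instant rise, exponential decay) at
#' each stimulation time, plus Gaussian noise; emulates a dopamine-sensor
#' ROI driven by brief depolarizing pulses delivered once per second after a
#' 60-s baseline.
#'
#' @param f0 baseline intensity, arbitrary units (> 0).
#' @param stim_times stimulation onsets, s; default one per second from 61 s
#'   to 120 s.
#' @param per_stim_dff transient amplitude as a fraction of `f0`.
#' @param decay_tau_s transient decay constant, s.
#' @param noise_sd Gaussian noise SD, a.u.
#' @param duration_s,sampling_rate trace length (s) and rate (Hz).
#' @param seed RNG seed.
#' @return A [fluorescence_trace()] (intensity clipped at 0).
#' @export
simulate_sniffer <- function(f0 = 100, stim_times = seq(61, 120, by = 1),
                             per_stim_dff = 0.5, decay_tau_s = 0.3,
                             noise_sd = 1, duration_s = 180,
                             sampling_rate = 50, seed = 1) {
  stopifnot(f0 > 0, decay_tau_s > 0)
  set.seed(seed)
  time <- seq(0, duration_s, by = 1 / sampling_rate)
  intensity <- rep(f0, length(time))
  for (ts in stim_times) {
    after <- time >= ts
    intensity[after] <- intensity[after] +
      per_stim_dff * f0 * exp(-(time[after] - ts) / decay_tau_s)
  }
  if (noise_sd > 0) intensity <- intensity + stats::rnorm(length(time), 0, noise_sd)
  fluorescence_trace(time, pmax(intensity, 0), roi_id = "sim",
                     stim_times = stim_times)
}
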