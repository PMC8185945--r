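# Independent oracles the implementation is checked against.  These are
# deliberately written as naive, literal translations of the definitions and
# share no code with the package internals.

# Explicit state machine for the ISI burst rule: OUT until a pair with
# ISI < onset opens a burst; IN while ISI <= offset; an ISI > offset (or the
# end of the train) closes it.
burst_oracle <- function(times, onset = 0.080, offset = 0.160, min_spikes = 2) {
  n <- length(times)
  member <- integer(n)         # 0 = not in a burst, k = burst id
  state <- "OUT"
  burst_id <- 0L
  current <- integer(0)
  close_burst <- function() {
    if (length(current) >= min_spikes) {
      burst_id <<- burst_id + 1L
      member[current] <<- burst_id
    }
    current <<- integer(0)
  }
  i <- 1L
  while (i < n) {
    isi <- times[i + 1L] - times[i]
    if (state == "OUT") {
      if (isi < onset) {
        current <- c(i, i + 1L)
        state <- "IN"
      }
    } else {
      if (isi <= offset) {
        current <- c(current, i + 1L)
      } else {
        close_burst()
        state <- "OUT"
      }
    }
    i <- i + 1L
  }
  if (state == "IN") close_burst()
  member
}

# burst membership vector from the package's detect_bursts output
burst_membership <- function(times, bursts) {
  member <- integer(length(times))
  for (k in seq_len(nrow(bursts)))
    member[bursts$first_spike[k]:bursts$last_spike[k]] <- k
  member
}

# sup over the pooled sample points of |ECDF_a - ECDF_b|
ks_D_oracle <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(x) mean(a <= x) - mean(b <= x), 0)))
}

# random spike trains mixing quasi-regular stretches and dense bursts, used
# for oracle-equivalence sweeps
random_spike_train <- function(n_spikes) {
  isis <- numeric(0)
  while (length(isis) < n_spikes - 1) {
    if (stats::runif(1) < 0.4) {
      k <- sample(2:12, 1)
      isis <- c(isis, stats::runif(k, 0.01, 0.25))   # straddles both thresholds
    } else {
      k <- sample(1:10, 1)
      isis <- c(isis, stats::rexp(k, rate = 1.5))
    }
  }
  cumsum(c(0, isis[seq_len(n_spikes - 1)]))
}

# voltage trace carrying Gaussian bumps at given peak times on a flat baseline
gaussian_spike_trace <- function(peak_times, amp_mv = 70, fwhm_ms = 2,
                                 baseline_mv = -60, duration_s = NULL,
                                 rate_hz = 10000, noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(duration_s)) duration_s <- max(peak_times) + 0.05
  t <- seq(0, duration_s, by = 1 / rate_hz)
  sigma <- fwhm_ms / 1000 / (2 * sqrt(2 * log(2)))
  v <- rep(baseline_mv, length(t))
  for (pt in peak_times) {
    pt <- t[which.min(abs(t - pt))]          # snap to grid
    win <- abs(t - pt) < 5 * sigma
    v[win] <- v[win] + amp_mv * exp(-(t[win] - pt)^2 / (2 * sigma^2))
  }
  if (noise_sd > 0) v <- v + stats::rnorm(length(t), 0, noise_sd)
  voltage_trace(t, v)
}
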