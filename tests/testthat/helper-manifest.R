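# small manifest of synthetic recordings written to disk, shared by the
# pipeline and determinism tests
make_manifest <- function(dir, duration_s = 30, corrupt = FALSE) {
  rows <- list()
  specs <- list(c("nas", 1), c("nas", 2), c("ast", 3), c("ast", 4))
  for (s in specs) {
    over <- if (s[1] == "ast") {
      # compress the burst/pause cycle so short test recordings hold bursts
      list(burst_duration_s = 6, burst_duration_sd_s = 1,
           burst_duration_range_s = c(4, 10), interburst_pause_s = 8,
           interburst_pause_sd_s = 2, interburst_pause_range_s = c(4, 15))
    } else list()
    cfg <- do.call(preset_config,
                   c(list(s[1], seed = as.integer(s[2]),
                          duration_s = duration_s, sampling_rate = 5000),
                     over))
    x <- simulate_trace(cfg)
    p <- file.path(dir, paste0(s[1], "_", s[2], ".csv"))
    write_trace(x$trace, p)
    rows[[length(rows) + 1]] <- data.frame(
      path = p, neuron_id = paste0(s[1], s[2]), group = toupper(s[1]))
  }
  if (corrupt) {
    p <- file.path(dir, "broken.csv")
    writeLines(c("0,-60", "0.1,-60", "0.05,-60"), p)  # non-monotone time
    rows[[length(rows) + 1]] <- data.frame(
      path = p, neuron_id = "broken1", group = "NAS")
  }
  do.call(rbind, rows)
}
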