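#' Construct a membrane-voltage trace
#'
#' A voltage trace is the substrate of all firing analysis: a uniformly
#' sampled membrane potential in millivolts with its sampling rate and
#' optional drug/stimulus epoch annotations.
#'
#' Time is kept in seconds everywhere inside the package; milliseconds appear
#' only in user-facing parameters that are conventionally quoted in ms
#' (refractory period, half-width, blanking window).
#'
#' @param time numeric, seconds, strictly increasing and uniformly spaced.
#' @param voltage numeric, millivolts, same length as `time`.
#' @param neuron_id character label for the recorded neuron.
#' @param group character group label (e.g. "NAS", "AST").
#' @param epochs optional data.frame with columns `label`, `start_s`, `end_s`
#'   annotating drug application or stimulation windows; must lie within the
#'   trace span.
#' @return An object of class `voltage_trace`: a list with `time`, `voltage`,
#'   `sampling_rate` (Hz, inferred from the median sample interval),
#'   `neuron_id`, `group`, `epochs`.
#' @export
voltage_trace <- function(time, voltage, neuron_id = "neuron", group = NA_character_,
                          epochs = NULL) {
  new_trace(time, voltage, "voltage", class = "voltage_trace",
            extra = list(neuron_id = neuron_id, group = group,
                         epochs = validate_epochs(epochs, time)))
}

#' Construct a voltage-clamp current trace
#'
#' Holds an evoked current (picoamps) recorded under voltage clamp, e.g. the
#' inward current produced by focal agonist application while the membrane is
#' held at -60 mV.
#'
#' @param time numeric, seconds, uniformly spaced.
#' @param current numeric, picoamps (inward currents negative).
#' @param holding_potential millivolts; the clamp potential.
#' @param application_onset_s seconds; time of focal drug application.
#' @return An object of class `current_trace`.
#' @export
current_trace <- function(time, current, holding_potential = -60,
                          application_onset_s = NA_real_) {
  new_trace(time, current, "current", class = "current_trace",
            extra = list(holding_potential = holding_potential,
                         application_onset_s = application_onset_s))
}

#' Construct an ROI fluorescence trace
#'
#' Holds the intensity time series of one region of interest from a
#' fluorescent-sensor recording, together with the stimulation times used for
#' stimulus-locked analysis.
#'
#' @param time numeric, seconds, uniformly spaced.
#' @param intensity numeric, arbitrary units, non-negative.
#' @param roi_id character label.
#' @param stim_times numeric, seconds; electrical stimulation onsets.
#' @return An object of class `fluorescence_trace`.
#' @export
fluorescence_trace <- function(time, intensity, roi_id = "roi",
                               stim_times = numeric(0)) {
  if (any(intensity < 0))
    stop("intensity must be non-negative (background subtraction happens upstream)")
  new_trace(time, intensity, "intensity", class = "fluorescence_trace",
            extra = list(roi_id = roi_id, stim_times = as.numeric(stim_times)))
}

# shared validation: uniform sampling, >= 2 samples, monotone time
new_trace <- function(time, value, value_name, class, extra = list()) {
  time <- as.numeric(time)
  value <- as.numeric(value)
  if (length(time) != length(value))
    stop("time and ", value_name, " must have equal length")
  if (length(time) < 2)
    stop("trace must have at least 2 samples")
  dt <- diff(time)
  if (any(dt <= 0))
    stop("time must be strictly increasing")
  med_dt <- stats::median(dt)
  if (any(abs(dt - med_dt) > 0.01 * med_dt))
    stop("non-uniform sampling: sample interval deviates > 1% from the median")
  obj <- c(list(time = time), stats::setNames(list(value), value_name),
           list(sampling_rate = 1 / med_dt), extra)
  structure(obj, class = class)
}

validate_epochs <- function(epochs, time) {
  if (is.null(epochs)) return(NULL)
  stopifnot(is.data.frame(epochs),
            all(c("label", "start_s", "end_s") %in% names(epochs)))
  if (any(epochs$end_s < epochs$start_s))
    stop("epoch with negative duration")
  if (any(epochs$start_s < time[1] - 1e-9) || any(epochs$end_s > time[length(time)] + 1e-9))
    stop("epoch outside trace span")
  epochs
}

#' @export
print.voltage_trace <- function(x, ...) {
  cat(sprintf("<voltage_trace> %s (%s): %d samples @ %.6g Hz, %.6g s\n",
              x$neuron_id, ifelse(is.na(x$group), "-", x$group),
              length(x$time), x$sampling_rate, x$time[length(x$time)] - x$time[1]))
  invisible(x)
}

#' @export
print.current_trace <- function(x, ...) {
  cat(sprintf("<current_trace> %d samples @ %.6g Hz, hold %.6g mV\n",
              length(x$time), x$sampling_rate, x$holding_potential))
  invisible(x)
}

#' @export
print.fluorescence_trace <- function(x, ...) {
  cat(sprintf("<fluorescence_trace> %s: %d samples @ %.6g Hz, %d stimuli\n",
              x$roi_id, length(x$time), x$sampling_rate, length(x$stim_times)))
  invisible(x)
}

#' Read a two-column time-series file as a trace
#'
#' Parses delimited text (CSV or TSV, comma/tab/semicolon autodetected from
#' the first data line, optional header) with time in seconds in the first
#' column and the signal in the second.  The sampling rate is inferred from
#' the median sample interval; traces whose sample interval varies by more
#' than 1% are rejected because the derivative-based spike detector assumes
#' uniform sampling.
#'
#' @param path file path.
#' @param kind one of "voltage", "current", "fluorescence"; selects the trace
#'   class and the units the second column is taken in (mV, pA, a.u.).
#' @param meta named list of extra fields passed to the matching constructor
#'   (e.g. `neuron_id`, `group`, `epochs`, `stim_times`,
#'   `holding_potential`).
#' @return A `voltage_trace`, `current_trace` or `fluorescence_trace`.
#' @export
read_trace <- function(path, kind = c("voltage", "current", "fluorescence"),
                       meta = list()) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty file: ", path)
  sep <- detect_sep(lines[[min(2, length(lines))]])
  first <- strsplit(lines[[1]], sep, fixed = TRUE)[[1]]
  has_header <- suppressWarnings(any(is.na(as.numeric(first[1:2]))))
  dat <- lines[if (has_header) -1L else TRUE]
  parts <- strsplit(dat, sep, fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 2L)
  if (length(bad))
    stop("malformed row at line ", bad[1] + has_header, " of ", path)
  tv <- vapply(parts, function(p) suppressWarnings(as.numeric(p[1:2])),
               numeric(2))
  if (anyNA(tv)) {
    bad <- which(apply(is.na(tv), 2, any))[1]
    stop("malformed row at line ", bad + has_header, " of ", path)
  }
  args <- c(list(tv[1, ], tv[2, ]), meta)
  switch(kind,
         voltage = do.call(voltage_trace, args),
         current = do.call(current_trace, args),
         fluorescence = do.call(fluorescence_trace, args))
}

detect_sep <- function(line) {
  for (s in c(",", "\t", ";")) if (grepl(s, line, fixed = TRUE)) return(s)
  ","
}

#' Write a trace to delimited text
#'
#' Writes two columns (`time_s` and the signal) as CSV with enough digits
#' that a read/write round trip preserves sample values to better than 1e-9.
#'
#' @param trace a trace object from [voltage_trace()], [current_trace()] or
#'   [fluorescence_trace()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  value_name <- trace_value_name(trace)
  df <- data.frame(time_s = trace$time, value = trace[[value_name]])
  names(df)[2] <- paste0(value_name, "_", trace_unit(trace))
  utils::write.csv(format(df, digits = 15, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

trace_value_name <- function(trace) {
  switch(class(trace)[1],
         voltage_trace = "voltage",
         current_trace = "current",
         fluorescence_trace = "intensity",
         stop("not a trace object"))
}

trace_unit <- function(trace) {
  switch(class(trace)[1],
         voltage_trace = "mv", current_trace = "pa", fluorescence_trace = "au")
}

#' Write result tables to disk
#'
#' Writes one CSV per named table plus a single JSON summary holding all
#' tables, with deterministic column order and numbers serialized at 9
#' significant digits, so repeated runs of the same analysis are
#' byte-identical.
#'
#' @param tables named list of data.frames.
#' @param out_dir output directory, created if missing.
#' @return Character vector of the files written (CSVs then JSON).
#' @export
write_results <- function(tables, out_dir) {
  if (!is.list(tables) || length(tables) == 0 || is.null(names(tables)) ||
      any(!nzchar(names(tables))))
    stop("tables must be a non-empty named list of data.frames")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  paths <- character(0)
  for (nm in names(tables)) {
    df <- as.data.frame(tables[[nm]])
    df <- df[, sort(names(df)), drop = FALSE]
    p <- file.path(out_dir, paste0(nm, ".csv"))
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], signif, digits = 9)
    utils::write.csv(df, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  jp <- file.path(out_dir, "summary.json")
  ordered <- lapply(tables[sort(names(tables))], function(df) {
    df <- as.data.frame(df)
    df[, sort(names(df)), drop = FALSE]
  })
  jsonlite::write_json(ordered, jp, digits = 9, dataframe = "columns",
                       na = "null", pretty = TRUE)
  c(paths, jp)
}
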