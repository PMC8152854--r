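#' Uniformly sampled voltage trace
#'
#' Container for a single-channel, uniformly sampled voltage time series.
#' All analysis functions in the package operate on `trace` objects; the
#' sampling rate travels with the samples so window lengths, filter corners
#' and wavelet scales can always be expressed in seconds and hertz.
#'
#' @param samples Numeric vector of voltage samples.
#' @param fs Sampling rate in Hz (> 0).
#' @param channel Channel label.
#' @param units Physical units of the samples (e.g. `"uV"`, `"mV"`).
#' @param t0 Time of the first sample in seconds.
#'
#' @return An object of class `trace`: a list with elements `samples`,
#'   `fs`, `channel`, `units`, `t0`.
#' @export
#' @examples
#' tr <- trace(sin(2 * pi * 5 * seq(0, 1, by = 1/500)), fs = 500)
#' duration(tr)
trace <- function(samples, fs, channel = "ch1", units = "uV", t0 = 0) {
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number", call. = FALSE)
  if (!is.numeric(samples) || length(samples) < 1L)
    stop("`samples` must be a non-empty numeric vector", call. = FALSE)
  structure(
    list(samples = as.numeric(samples), fs = as.numeric(fs),
         channel = as.character(channel), units = as.character(units),
         t0 = as.numeric(t0)),
    class = "trace")
}

#' @export
print.trace <- function(x, ...) {
  cat(sprintf("<trace> channel=%s  n=%d  fs=%g Hz  duration=%.3f s  units=%s\n",
              x$channel, length(x$samples), x$fs, duration(x), x$units))
  invisible(x)
}

#' Trace duration in seconds
#' @param x A `trace`.
#' @return Duration (n samples / fs) in seconds.
#' @export
duration <- function(x) length(x$samples) / x$fs

#' Time axis of a trace
#' @param x A `trace`.
#' @return Numeric vector of sample times in seconds (starting at `t0`).
#' @export
time_axis <- function(x) x$t0 + (seq_along(x$samples) - 1L) / x$fs

# sample index of time t (seconds, absolute), clamped to [1, n]
.t2i <- function(x, t) {
  i <- round((t - x$t0) * x$fs) + 1L
  pmin(pmax(i, 1L), length(x$samples))
}

#' Extract a time segment of a trace
#'
#' @param x A `trace`.
#' @param from,to Segment bounds in seconds (absolute, half-open `[from, to)`).
#' @return A `trace` holding the samples in the window; `t0` is updated.
#' @export
trace_window <- function(x, from, to) {
  stopifnot(to > from)
  i0 <- .t2i(x, from)
  i1 <- max(i0, .t2i(x, to) - 1L)
  trace(x$samples[i0:i1], x$fs, x$channel, x$units,
        t0 = x$t0 + (i0 - 1L) / x$fs)
}

#' Event annotation table
#'
#' Builds the standard event table used across the package: one row per
#' event with identifier, channel, kind, onset and termination times and a
#' free-form JSON attribute string. Rows are sorted by onset.
#'
#' @param event_id Integer or character ids.
#' @param channel Channel labels.
#' @param kind Event kind labels (e.g. `"discharge"`, `"SPW"`, `"interictal"`).
#' @param onset_s,termination_s Event bounds in seconds; onset must precede
#'   termination row-wise.
#' @param params_json Optional per-event attribute strings (default `""`).
#' @return A `data.frame` with the columns above, sorted by `onset_s`.
#' @export
event_table <- function(event_id = integer(), channel = character(),
                        kind = character(), onset_s = numeric(),
                        termination_s = numeric(), params_json = NULL) {
  n <- length(onset_s)
  if (is.null(params_json)) params_json <- rep("", n)
  df <- data.frame(event_id = event_id, channel = channel, kind = kind,
                   onset_s = onset_s, termination_s = termination_s,
                   params_json = params_json, stringsAsFactors = FALSE)
  if (n && any(df$termination_s <= df$onset_s))
    stop("event_table: onset_s must precede termination_s", call. = FALSE)
  df[order(df$onset_s), , drop = FALSE]
}
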