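# Trace and event-table I/O.
#
# Two trace formats are supported: a plain-text CSV dialect (header lines
# `fs=`, `units=`, `channel=`, optionally `t0=`, then one sample per line)
# and a minimal EDF subset (continuous recording, one data record holding
# the whole trace, 16-bit samples over a symmetric physical range). Event
# tables travel as ordinary CSV with the standard columns.

#' Read a voltage trace
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"csv"` or `"edf"`.
#' @param channel For EDF files with several signals: the label or index of
#'   the channel to return (default first).
#' @return A `trace`.
#' @export
read_trace <- function(path, format = c("auto", "csv", "edf"), channel = 1L) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  if (format == "csv") .read_trace_csv(path) else {
    trs <- read_edf(path)
    if (is.character(channel)) {
      hit <- which(vapply(trs, function(t) t$channel == channel, logical(1)))
      if (!length(hit)) stop("channel not found: ", channel, call. = FALSE)
      channel <- hit[1]
    }
    trs[[channel]]
  }
}

#' Write a voltage trace
#'
#' @param x A `trace` (or for EDF a list of traces with equal `fs` and
#'   length).
#' @param path Destination path.
#' @param format `"auto"` (by extension), `"csv"` or `"edf"`.
#' @return `path`, invisibly.
#' @export
write_trace <- function(x, path, format = c("auto", "csv", "edf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  if (format == "csv") {
    stopifnot(inherits(x, "trace"))
    .write_trace_csv(x, path)
  } else write_edf(x, path)
  invisible(path)
}

.write_trace_csv <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("fs=%.10g", x$fs), sprintf("units=%s", x$units),
               sprintf("channel=%s", x$channel), sprintf("t0=%.10g", x$t0)),
             con)
  writeLines(formatC(x$samples, format = "g", digits = 10), con)
}

.read_trace_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^[A-Za-z_][A-Za-z0-9_]*=", lines)
  if (!length(hdr) || any(diff(hdr) != 1) || hdr[1] != 1)
    stop("malformed trace CSV: header lines (fs=, units=, channel=) must lead the file",
         call. = FALSE)
  kv <- strsplit(lines[hdr], "=", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, function(p) paste(p[-1], collapse = "="), "")
  if (!"fs" %in% keys)
    stop("malformed trace CSV: missing fs= header", call. = FALSE)
  fs <- as.numeric(vals[keys == "fs"][1])
  if (!is.finite(fs) || fs <= 0)
    stop("malformed trace CSV: fs is not a positive number", call. = FALSE)
  getv <- function(k, default) if (k %in% keys) vals[keys == k][1] else default
  samples <- suppressWarnings(as.numeric(lines[-hdr]))
  if (anyNA(samples))
    stop("malformed trace CSV: non-numeric sample line", call. = FALSE)
  trace(samples, fs, channel = getv("channel", "ch1"),
        units = getv("units", "uV"), t0 = as.numeric(getv("t0", "0")))
}

# --- minimal EDF subset ----------------------------------------------------

.pad <- function(s, n) formatC(as.character(s), width = -n)  # left-justified

#' Write traces to a minimal EDF file
#'
#' Writes one or more equal-length, equal-rate traces as a single-record
#' EDF file (16-bit samples over a symmetric physical range per channel).
#' Intended for analysis exports and round-tripping within this package;
#' the full EDF feature set (discontinuous records, annotations, per-signal
#' rates) is out of scope.
#'
#' @param x A `trace` or list of `trace` objects (equal `fs` and length).
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(x, path) {
  trs <- if (inherits(x, "trace")) list(x) else x
  stopifnot(all(vapply(trs, inherits, logical(1), "trace")))
  fs <- trs[[1]]$fs; n <- length(trs[[1]]$samples)
  if (!all(vapply(trs, function(t) t$fs == fs && length(t$samples) == n,
                  logical(1))))
    stop("all channels must share fs and length", call. = FALSE)
  ns <- length(trs)
  rec_dur <- n / fs
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, w) writeChar(.pad(s, w), con, nchars = w, eos = NULL)
  wr("0", 8); wr("synthetic", 80); wr("ictalwave export", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(256 * (ns + 1), 8); wr("", 44); wr(1, 8)
  wr(formatC(rec_dur, format = "g", digits = 7), 8); wr(ns, 4)
  pmax_ <- vapply(trs, function(t) max(abs(t$samples), 1e-12), numeric(1))
  for (t in trs) wr(t$channel, 16)
  for (t in trs) wr("", 80)
  for (t in trs) wr(t$units, 8)
  for (p in pmax_) wr(formatC(-p, format = "g", digits = 7), 8)
  for (p in pmax_) wr(formatC(p, format = "g", digits = 7), 8)
  for (t in trs) wr(-32768, 8)
  for (t in trs) wr(32767, 8)
  for (t in trs) wr("", 80)
  for (t in trs) wr(n, 8)
  for (t in trs) wr("", 32)
  for (k in seq_len(ns)) {
    dig <- as.integer(round(trs[[k]]$samples / pmax_[k] * 32767))
    writeBin(dig, con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a minimal EDF file
#'
#' @param path EDF file path.
#' @return A list of `trace` objects, one per signal.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  hdr_bytes <- as.integer(rd(8)); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop("malformed EDF: signal count", call. = FALSE)
  labs <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  units <- vapply(seq_len(ns), function(i) rd(8), "")
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  if (anyNA(c(pmin_, pmax_, dmin, dmax, spr, n_rec, rec_dur)))
    stop("malformed EDF: numeric header field", call. = FALSE)
  sig <- vector("list", ns)
  for (r in seq_len(n_rec)) {
    for (k in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[k], size = 2, signed = TRUE,
                     endian = "little")
      phys <- pmin_[k] + (dig - dmin[k]) * (pmax_[k] - pmin_[k]) / (dmax[k] - dmin[k])
      sig[[k]] <- c(sig[[k]], phys)
    }
  }
  lapply(seq_len(ns), function(k)
    trace(sig[[k]], fs = spr[k] / rec_dur, channel = labs[k],
          units = units[k]))
}

# --- event tables and configs ---------------------------------------------

#' Write an event table as CSV
#' @param events An [event_table()].
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' Read an event table from CSV
#' @param path CSV path with the standard event columns.
#' @return An [event_table()].
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("event_id", "channel", "kind", "onset_s", "termination_s")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("event CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!"params_json" %in% names(df)) df$params_json <- ""
  event_table(df$event_id, df$channel, df$kind, df$onset_s, df$termination_s,
              df$params_json)
}

#' Read detector parameters from a YAML file
#'
#' Fields not present in the file keep their [detection_params()] defaults.
#'
#' @param path YAML file path.
#' @return A [detection_params()] object.
#' @export
read_detection_params <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(detection_params, y[intersect(names(y),
                                        names(formals(detection_params)))])
}

#' Write detector parameters to YAML
#' @param params A [detection_params()].
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_detection_params <- function(params, path) {
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}
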