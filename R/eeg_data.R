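#' Labeled multichannel EEG trial set
#'
#' Container for a set of cue-aligned EEG trials: a numeric array of
#' dimension trials x channels x samples (microvolts), the sampling rate,
#' a per-trial class label in \{1, 2\} (1 = left hand, 2 = right hand),
#' ordered channel names, and the time of sample index 1 relative to cue
#' onset.  Sample i of a trial occurs at \code{t0 + (i - 1) / fs} seconds.
#'
#' @param data numeric array, trials x channels x samples.
#' @param fs sampling rate in Hz (> 0).
#' @param labels integer vector of per-trial class codes in \{1, 2\}.
#' @param channel_names character vector of channel identifiers, no
#'   duplicates, length equal to \code{dim(data)[2]}.
#' @param t0 time of the first sample relative to cue onset, seconds.
#' @return an object of class \code{eeg_trial_set}.
#' @export
eeg_trial_set <- function(data, fs, labels, channel_names, t0 = 0) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-d array (trials x channels x samples)")
  storage.mode(data) <- "double"
  if (!all(is.finite(data)))
    stop("trial data contains non-finite values")
  if (length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number")
  labels <- as.integer(labels)
  if (length(labels) != dim(data)[1L])
    stop("length(labels) must equal the number of trials")
  bad <- setdiff(unique(labels), c(1L, 2L))
  if (length(bad) > 0)
    stop("unknown label codes: ", paste(bad, collapse = ", "),
         " (labels must be 1 or 2)")
  channel_names <- as.character(channel_names)
  if (length(channel_names) != dim(data)[2L])
    stop("length(channel_names) must equal the number of channels")
  if (anyDuplicated(channel_names))
    stop("duplicate channel names")
  structure(
    list(data = data, fs = as.numeric(fs), labels = labels,
         channel_names = channel_names, t0 = as.numeric(t0)),
    class = "eeg_trial_set")
}

#' @export
print.eeg_trial_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<eeg_trial_set> %d trials x %d channels (%s) x %d samples @ %g Hz\n",
    d[1], d[2], paste(x$channel_names, collapse = ", "), d[3], x$fs))
  cat(sprintf("  t = [%.3f, %.3f) s relative to cue; labels: %s\n",
              x$t0, x$t0 + d[3] / x$fs,
              paste(sprintf("%d x class %d", tabulate(x$labels, 2), 1:2),
                    collapse = ", ")))
  invisible(x)
}

#' Number of trials / channels / samples of a trial set
#' @param ts an \code{eeg_trial_set}.
#' @return integer.
#' @export
n_trials <- function(ts) dim(ts$data)[1L]

#' @rdname n_trials
#' @export
n_channels <- function(ts) dim(ts$data)[2L]

#' @rdname n_trials
#' @export
n_samples <- function(ts) dim(ts$data)[3L]

#' Subset or reorder the channels of a trial set
#'
#' @param ts an \code{eeg_trial_set}.
#' @param names ordered channel identifiers to keep; every name must be
#'   present in \code{ts$channel_names}.
#' @return an \code{eeg_trial_set} restricted to \code{names}, in that
#'   order; all other fields unchanged.
#' @export
select_channels <- function(ts, names) {
  stopifnot(inherits(ts, "eeg_trial_set"))
  missing <- setdiff(names, ts$channel_names)
  if (length(missing) > 0)
    stop("channel(s) not present: ", paste(missing, collapse = ", "))
  idx <- match(names, ts$channel_names)
  eeg_trial_set(ts$data[, idx, , drop = FALSE], ts$fs, ts$labels,
                ts$channel_names[idx], ts$t0)
}

#' Zero-phase band-pass filter every trial and channel
#'
#' A 4th-order Butterworth band-pass applied forward and backward
#' (\code{signal::filtfilt}), so the filtered signal has no phase lag
#' relative to the cue-aligned time axis.
#'
#' @param ts an \code{eeg_trial_set}.
#' @param lo,hi band edges in Hz; \code{0 < lo < hi < fs/2}.
#' @param order filter order of the underlying Butterworth prototype.
#' @return an \code{eeg_trial_set} of identical shape.
#' @export
bandpass <- function(ts, lo, hi, order = 4L) {
  stopifnot(inherits(ts, "eeg_trial_set"))
  nyq <- ts$fs / 2
  if (!(lo > 0 && lo < hi))
    stop("require 0 < lo < hi")
  if (hi >= nyq)
    stop(sprintf("upper edge %g Hz must be below the Nyquist frequency %g Hz",
                 hi, nyq))
  bf <- signal::butter(order, c(lo, hi) / nyq, type = "pass")
  out <- ts$data
  nt <- dim(out)[1L]; nc <- dim(out)[2L]
  for (i in seq_len(nt))
    for (c in seq_len(nc))
      out[i, c, ] <- signal::filtfilt(bf, out[i, c, ])
  eeg_trial_set(out, ts$fs, ts$labels, ts$channel_names, ts$t0)
}

#' Crop every trial to a cue-relative time window
#'
#' Keeps the samples whose times fall in the half-open interval
#' \code{[t_start, t_end)} relative to cue onset, and updates \code{t0}.
#' A window of width w seconds therefore always yields exactly
#' \code{round(w * fs)} samples.
#'
#' @param ts an \code{eeg_trial_set}.
#' @param t_start,t_end window limits in seconds after cue onset; the
#'   window must lie within the recorded extent.
#' @return the cropped \code{eeg_trial_set} with \code{t0 = t_start}.
#' @export
crop <- function(ts, t_start, t_end) {
  stopifnot(inherits(ts, "eeg_trial_set"), t_start < t_end)
  L <- n_samples(ts)
  rec_end <- ts$t0 + L / ts$fs
  # sample i (1-based) is at t0 + (i-1)/fs; round() guards float jitter
  i0 <- round((t_start - ts$t0) * ts$fs) + 1
  i1 <- round((t_end - ts$t0) * ts$fs)
  if (i0 < 1 || i1 > L)
    stop(sprintf(
      "window [%g, %g) outside recorded extent [%g, %g) s relative to cue",
      t_start, t_end, ts$t0, rec_end))
  eeg_trial_set(ts$data[, , i0:i1, drop = FALSE], ts$fs, ts$labels,
                ts$channel_names, t_start)
}

#' Read a labeled trial set from disk
#'
#' Supported formats: \code{"columnar"} -- the package's native plain-text
#' trial format (see \code{\link{write_trials_columnar}} for the schema);
#' \code{"edf"} -- minimal European Data Format support, one data record
#' per trial, with labels and the cue-relative time origin carried in a
#' plain-text sidecar file \code{<path>.labels} written by
#' \code{\link{write_trials_edf}}.  GDF is not supported; convert to EDF
#' or columnar first.
#'
#' @param path file to read.
#' @param format one of \code{"columnar"}, \code{"edf"}.
#' @return a validated \code{eeg_trial_set}; trial order as stored.
#' @export
load_trials <- function(path, format = c("columnar", "edf", "gdf")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("cannot read trial file: ", path)
  switch(format,
         columnar = read_trials_columnar(path),
         edf = read_trials_edf(path),
         gdf = stop("GDF reading is not supported; convert to EDF or the ",
                    "columnar format first"))
}

# ---- native columnar trial format ------------------------------------------
#
# Plain-text schema (one file per trial set):
#   line 1: "miwave-trials 1"          (magic + schema version)
#   header lines "key: value" until a blank line:
#     fs: <Hz>   t0: <s>   channels: <comma list>   labels: <comma list>
#     n_trials: <int>      n_samples: <int>
#   then for each trial, a line "trial <i>" followed by n_samples rows of
#   n_channels whitespace-separated numbers printed with %.17g (so the
#   read-back doubles are bit-identical to the written ones).

#' Write a trial set in the native columnar text format
#'
#' The round trip \code{load_trials(write_trials_columnar(ts, f))} is
#' bit-exact: samples are printed with 17 significant digits.
#'
#' @param ts an \code{eeg_trial_set}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_trials_columnar <- function(ts, path) {
  stopifnot(inherits(ts, "eeg_trial_set"))
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) stop("cannot write to: ", path),
                  warning = function(w) stop("cannot write to: ", path))
  on.exit(close(con))
  d <- dim(ts$data)
  writeLines(c(
    "miwave-trials 1",
    sprintf("fs: %.17g", ts$fs),
    sprintf("t0: %.17g", ts$t0),
    paste0("channels: ", paste(ts$channel_names, collapse = ",")),
    paste0("labels: ", paste(ts$labels, collapse = ",")),
    sprintf("n_trials: %d", d[1]),
    sprintf("n_samples: %d", d[3]),
    ""), con)
  for (i in seq_len(d[1])) {
    writeLines(sprintf("trial %d", i), con)
    block <- t(ts$data[i, , , drop = TRUE])          # samples x channels
    if (d[2] == 1L) block <- matrix(block, ncol = 1L)
    writeLines(apply(matrix(sprintf("%.17g", block), nrow = d[3]),
                     1L, paste, collapse = " "), con)
  }
  invisible(path)
}

read_trials_columnar <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 8L || lines[1] != "miwave-trials 1")
    stop("not a miwave columnar trial file: ", path)
  hdr_end <- which(lines == "")[1]
  hdr <- lines[2:(hdr_end - 1)]
  kv <- strsplit(hdr, ": ", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = ": "), "")
  need <- c("fs", "t0", "channels", "labels", "n_trials", "n_samples")
  if (!all(need %in% keys))
    stop("columnar header missing field(s): ",
         paste(setdiff(need, keys), collapse = ", "))
  g <- function(k) vals[match(k, keys)]
  fs <- as.numeric(g("fs")); t0 <- as.numeric(g("t0"))
  channels <- strsplit(g("channels"), ",", fixed = TRUE)[[1]]
  labels <- as.integer(strsplit(g("labels"), ",", fixed = TRUE)[[1]])
  ntr <- as.integer(g("n_trials")); ns <- as.integer(g("n_samples"))
  nc <- length(channels)
  body <- lines[(hdr_end + 1):length(lines)]
  body <- body[nzchar(body)]
  dat <- array(NA_real_, c(ntr, nc, ns))
  pos <- 1L
  bad_trials <- integer(0)
  for (i in seq_len(ntr)) {
    if (pos > length(body) || !startsWith(body[pos], "trial ")) {
      bad_trials <- c(bad_trials, i); break
    }
    pos <- pos + 1L
    rows <- body[pos:min(pos + ns - 1L, length(body))]
    rows <- rows[!startsWith(rows, "trial ")]
    vals_i <- suppressWarnings(
      lapply(strsplit(trimws(rows), "[[:space:]]+"), as.numeric))
    ok <- length(rows) == ns &&
      all(vapply(vals_i, length, 0L) == nc) &&
      all(vapply(vals_i, function(v) all(is.finite(v)), TRUE))
    if (!ok) { bad_trials <- c(bad_trials, i); pos <- pos + length(rows) ; next }
    dat[i, , ] <- t(do.call(rbind, vals_i))
    pos <- pos + ns
  }
  if (length(bad_trials) > 0)
    stop("inconsistent or malformed trial block(s): trial ",
         paste(bad_trials, collapse = ", "))
  eeg_trial_set(dat, fs, labels, channels, t0)
}

# ---- minimal EDF support ----------------------------------------------------
#
# EDF stores int16 samples against a per-channel physical range, so the
# round trip is exact only up to the 16-bit quantization step
# (phys_range / 65535).  One EDF data record per trial.  EDF itself has
# no per-trial label field; labels and t0 travel in "<path>.labels", a
# two-line text sidecar.

#' Write a trial set as a minimal EDF file
#'
#' @param ts an \code{eeg_trial_set}.
#' @param path output file path; a sidecar \code{<path>.labels} carries
#'   the per-trial labels and the cue-relative time origin.
#' @return \code{path}, invisibly.
#' @export
write_trials_edf <- function(ts, path) {
  stopifnot(inherits(ts, "eeg_trial_set"))
  d <- dim(ts$data)
  ntr <- d[1]; nc <- d[2]; ns <- d[3]
  # physical range must survive its 8-char ASCII header field, so format
  # first and digitize against the value as parsed back
  phys_str <- formatC(max(abs(ts$data), 1e-9) * 1.001, format = "g",
                      digits = 5, width = 1)
  if (nchar(phys_str) > 7) phys_str <- formatC(as.numeric(phys_str) * 1.1,
                                               format = "e", digits = 2)
  phys_max <- as.numeric(phys_str)
  dig_max <- 32767L
  pad <- function(x, w) formatC(as.character(x), width = w, flag = "-")
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) stop("cannot write to: ", path),
                  warning = function(w) stop("cannot write to: ", path))
  on.exit(close(con))
  hdr <- paste0(
    pad("0", 8), pad("X X X X", 80), pad("Startdate X X X X", 80),
    pad("01.01.00", 8), pad("00.00.00", 8),
    pad(256L * (nc + 1L), 8), pad("", 44), pad(ntr, 8),
    pad(format(ns / ts$fs, digits = 8), 8), pad(nc, 4))
  writeChar(hdr, con, eos = NULL)
  writeChar(paste0(vapply(ts$channel_names, pad, "", w = 16), collapse = ""),
            con, eos = NULL)
  writeChar(strrep(pad("EEG electrode", 80), nc), con, eos = NULL)
  writeChar(strrep(pad("uV", 8), nc), con, eos = NULL)
  writeChar(strrep(pad(paste0("-", phys_str), 8), nc), con, eos = NULL)
  writeChar(strrep(pad(phys_str, 8), nc), con, eos = NULL)
  writeChar(strrep(pad(-32768L, 8), nc), con, eos = NULL)
  writeChar(strrep(pad(dig_max, 8), nc), con, eos = NULL)
  writeChar(strrep(pad("", 80), nc), con, eos = NULL)
  writeChar(strrep(pad(ns, 8), nc), con, eos = NULL)
  writeChar(strrep(pad("", 32), nc), con, eos = NULL)
  scale <- (dig_max - (-32768)) / (2 * phys_max)
  for (i in seq_len(ntr))
    for (c in seq_len(nc)) {
      dig <- as.integer(round((ts$data[i, c, ] + phys_max) * scale) - 32768)
      writeBin(pmin(pmax(dig, -32768L), 32767L), con, size = 2L,
               endian = "little")
    }
  writeLines(c(paste(ts$labels, collapse = ","),
               sprintf("%.17g", ts$t0)),
             paste0(path, ".labels"))
  invisible(path)
}

read_trials_edf <- function(path) {
  con <- file(path, open = "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8); rd(44)
  ntr <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  nc <- as.integer(rd(4))
  channels <- vapply(seq_len(nc), function(i) rd(16), "")
  rd(80 * nc); rd(8 * nc)
  pmin_ <- as.numeric(vapply(seq_len(nc), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(nc), function(i) rd(8), ""))
  dmin_ <- as.numeric(vapply(seq_len(nc), function(i) rd(8), ""))
  dmax_ <- as.numeric(vapply(seq_len(nc), function(i) rd(8), ""))
  rd(80 * nc)
  ns_ <- as.integer(vapply(seq_len(nc), function(i) rd(8), ""))
  rd(32 * nc)
  if (length(unique(ns_)) != 1L)
    stop("EDF channels disagree on samples per record; unsupported")
  ns <- ns_[1]
  fs <- ns / rec_dur
  dat <- array(NA_real_, c(ntr, nc, ns))
  for (i in seq_len(ntr))
    for (c in seq_len(nc)) {
      dig <- readBin(con, "integer", n = ns, size = 2L, signed = TRUE,
                     endian = "little")
      dat[i, c, ] <- pmin_[c] +
        (dig - dmin_[c]) * (pmax_[c] - pmin_[c]) / (dmax_[c] - dmin_[c])
    }
  side <- paste0(path, ".labels")
  if (file.exists(side)) {
    sl <- readLines(side)
    labels <- as.integer(strsplit(sl[1], ",", fixed = TRUE)[[1]])
    t0 <- as.numeric(sl[2])
  } else {
    warning("no label sidecar found for ", path, "; assuming class 1, t0 = 0")
    labels <- rep(1L, ntr); t0 <- 0
  }
  eeg_trial_set(dat, fs, labels, channels, t0)
}
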