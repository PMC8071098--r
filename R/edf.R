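# Minimal European Data Format (EDF) reader/writer: single-channel,
# contiguous 16-bit records, one data record per second. EDF+ annotations,
# multi-channel montages and BDF are out of scope.

edf_field <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) s <- substr(s, 1, width)
  formatC(s, width = -width)
}

# Physical min/max are stored as 8-char ASCII; format them first and use the
# parsed-back values for digital encoding so read(write(x)) stays consistent.
edf_num_field <- function(x, width = 8) {
  s <- formatC(signif(x, 6), width = -width, format = "g")
  if (nchar(s) > width) s <- substr(s, 1, width)
  s
}

#' Write a recording to a European Data Format (EDF) file
#'
#' Writes a standard-conformant single-channel EDF file: 16-bit samples, one
#' data record per second. The physical range is chosen to cover the signal
#' range (widened symmetrically for a constant signal, which would otherwise
#' give a degenerate scaling). Amplitudes are stored in the recording's own
#' units.
#'
#' @param recording An [eeg_recording()]; `fs` must be a positive integer
#'   (samples per 1 s record) and the duration a whole number of seconds
#'   (a trailing fraction of a second is dropped with a warning).
#' @param path Output file path.
#' @param physical_dim Physical dimension string stored in the header
#'   (default `"uV"`; synthetic recordings are arbitrary units).
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path, physical_dim = "uV") {
  stopifnot(inherits(recording, "eeg_recording"))
  x <- recording$samples
  if (!all(is.finite(x))) stop_validation("recording has non-finite samples")
  fs <- recording$fs
  if (fs != round(fs) || fs <= 0) {
    stop_validation("EDF writer requires an integer sampling rate")
  }
  fs <- as.integer(fs)
  n_rec <- length(x) %/% fs
  if (n_rec < 1L) {
    stop_validation("recording shorter than one 1 s data record")
  }
  if (n_rec * fs < length(x)) {
    warning(sprintf(
      "dropping %d trailing samples (partial final record)",
      length(x) - n_rec * fs
    ))
    x <- x[seq_len(n_rec * fs)]
  }

  pmin_raw <- min(x)
  pmax_raw <- max(x)
  if (pmax_raw - pmin_raw <= 0) {
    half <- max(1, abs(pmin_raw))
    pmin_raw <- pmin_raw - half
    pmax_raw <- pmax_raw + half
  }
  pmin_s <- edf_num_field(pmin_raw)
  pmax_s <- edf_num_field(pmax_raw)
  pmin <- as.numeric(pmin_s)
  pmax <- as.numeric(pmax_s)
  if (!(pmin <= min(x) && pmax >= max(x))) {
    # rounding of the ASCII fields must never clip the signal
    span <- pmax_raw - pmin_raw
    pmin_s <- edf_num_field(pmin_raw - 0.01 * span)
    pmax_s <- edf_num_field(pmax_raw + 0.01 * span)
    pmin <- as.numeric(pmin_s)
    pmax <- as.numeric(pmax_s)
  }
  dmin <- -32768L
  dmax <- 32767L
  dig <- as.integer(round((x - pmin) / (pmax - pmin) * (dmax - dmin) + dmin))
  dig <- pmin(pmax(dig, dmin), dmax)

  st <- recording$start_time
  if (is.null(st)) st <- as.POSIXct("2000-01-01 00:00:00", tz = "UTC")
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_field("0", 8),
    edf_field("X X X X", 80),
    edf_field("Startdate X X X X", 80),
    edf_field(format(st, "%d.%m.%y"), 8),
    edf_field(format(st, "%H.%M.%S"), 8),
    edf_field(256 + 256 * 1, 8),
    edf_field("", 44),
    edf_field(n_rec, 8),
    edf_field("1", 8),
    edf_field(1, 4),
    # per-signal header (one signal)
    edf_field(recording$channel_name, 16),
    edf_field("", 80),
    edf_field(physical_dim, 8),
    edf_field(pmin_s, 8),
    edf_field(pmax_s, 8),
    edf_field(dmin, 8),
    edf_field(dmax, 8),
    edf_field("", 80),
    edf_field(fs, 8),
    edf_field("", 32)
  )
  writeChar(hdr, con, nchars = nchar(hdr), eos = NULL)
  writeBin(dig, con, size = 2L, endian = "little")
  invisible(path)
}

#' Read a single channel from a European Data Format (EDF) file
#'
#' Parses the EDF header, selects one signal, and converts 16-bit digital
#' samples to physical units using the header's physical/digital scaling
#' fields. EDF+ annotation signals and discontinuous files are not
#' supported.
#'
#' @param path Path to an EDF file.
#' @param channel Channel to read: 1-based index or label; default the
#'   first signal.
#' @return An [eeg_recording()] in the file's physical units.
#' @export
read_edf <- function(path, channel = 1L) {
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path))
  fsize <- file.info(path)$size
  if (fsize < 256) {
    stop_io(sprintf(
      "truncated EDF: file is %d bytes, fixed header needs 256 (offset 0-255)",
      fsize
    ))
  }
  con <- file(path, "rb")
  on.exit(close(con))
  read_str <- function(n) {
    trimws(readChar(con, n, useBytes = TRUE))
  }
  read_num <- function(n) {
    v <- suppressWarnings(as.numeric(read_str(n)))
    if (is.na(v)) stop_io("malformed EDF header: non-numeric field")
    v
  }
  version <- read_str(8)
  if (version != "0") stop_io(sprintf("unsupported EDF version '%s'", version))
  read_str(80) # patient id
  read_str(80) # recording id
  date_s <- read_str(8)
  time_s <- read_str(8)
  header_bytes <- read_num(8)
  read_str(44) # reserved
  n_rec <- read_num(8)
  rec_dur <- read_num(8)
  ns <- as.integer(read_num(4))
  if (ns < 1) stop_io("EDF file declares no signals")
  if (fsize < header_bytes) {
    stop_io(sprintf(
      "truncated EDF: file is %d bytes, header claims %d (signal headers end at offset %d)",
      fsize, header_bytes, as.integer(header_bytes) - 1L
    ))
  }
  sig_field <- function(width) {
    vapply(seq_len(ns), function(i) trimws(readChar(con, width, useBytes = TRUE)),
           character(1))
  }
  labels <- sig_field(16)
  sig_field(80) # transducer
  sig_field(8)  # physical dimension
  pmin <- as.numeric(sig_field(8))
  pmax <- as.numeric(sig_field(8))
  dmin <- as.numeric(sig_field(8))
  dmax <- as.numeric(sig_field(8))
  sig_field(80) # prefiltering
  spr <- as.integer(sig_field(8)) # samples per record, per signal
  sig_field(32) # reserved
  if (anyNA(c(pmin, pmax, dmin, dmax, spr))) {
    stop_io("malformed EDF header: non-numeric signal scaling fields")
  }

  if (is.character(channel)) {
    ch <- match(channel, labels)
    if (is.na(ch)) {
      stop_io(sprintf(
        "channel '%s' absent (available: %s)", channel,
        paste(labels, collapse = ", ")
      ))
    }
  } else {
    ch <- as.integer(channel)
    if (ch < 1L || ch > ns) {
      stop_io(sprintf("channel index %d out of range 1..%d", ch, ns))
    }
  }

  rec_bytes <- sum(spr) * 2L
  if (n_rec < 0) n_rec <- (fsize - header_bytes) %/% rec_bytes
  n_rec <- as.integer(n_rec)
  expected <- header_bytes + n_rec * rec_bytes
  if (fsize < expected) {
    n_full <- (fsize - header_bytes) %/% rec_bytes
    stop_io(sprintf(
      "truncated EDF: expected %d bytes, got %d (data truncated at offset %d, record %d of %d)",
      as.integer(expected), fsize,
      as.integer(header_bytes + n_full * rec_bytes), n_full + 1L, n_rec
    ))
  }

  out <- numeric(n_rec * spr[ch])
  offs <- c(0L, cumsum(spr))
  for (r in seq_len(n_rec)) {
    rec <- readBin(con, "integer", n = sum(spr), size = 2L, signed = TRUE,
                   endian = "little")
    out[((r - 1L) * spr[ch] + 1L):(r * spr[ch])] <-
      rec[(offs[ch] + 1L):offs[ch + 1L]]
  }
  gain <- (pmax[ch] - pmin[ch]) / (dmax[ch] - dmin[ch])
  phys <- (out - dmin[ch]) * gain + pmin[ch]

  start_time <- tryCatch(
    as.POSIXct(paste(date_s, time_s), format = "%d.%m.%y %H.%M.%S", tz = "UTC"),
    error = function(e) NULL
  )
  fs <- spr[ch] / rec_dur
  eeg_recording(phys, fs = fs, channel_name = labels[ch],
                start_time = start_time)
}

#' Write per-epoch labels to a sidecar CSV
#'
#' @param labels Data.frame with columns `epoch_index`, `label` and
#'   optionally `subject` (as produced by [generate_recording()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_epoch_labels <- function(labels, path) {
  if (!all(c("epoch_index", "label") %in% names(labels))) {
    stop_validation("labels need columns `epoch_index` and `label`")
  }
  utils::write.csv(labels, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read per-epoch labels from a sidecar CSV
#'
#' @param path CSV with columns `epoch_index,label[,subject]`.
#' @return Data.frame ordered by `epoch_index`.
#' @export
read_epoch_labels <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("labels file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("epoch_index", "label") %in% names(df))) {
    stop_io("labels CSV must have columns epoch_index,label")
  }
  df[order(df$epoch_index), , drop = FALSE]
}
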