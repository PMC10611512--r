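# Minimal EDF (European Data Format) writer/reader: 16-bit samples, one
# data record per second, identical physical scaling for all channels of a
# file. Covers the interchange needs of this package (no annotations, no
# discontinuous records).

#' Write a multichannel signal to an EDF file
#'
#' @param data channels x samples numeric matrix.
#' @param fs sampling rate (Hz); must be an integer (one data record per
#'   second).
#' @param file output path.
#' @param channel_names one label per channel.
#' @param physical_dim physical dimension string (e.g. "uV", "mV").
#' @return the file path, invisibly.
#' @export
write_edf <- function(data, fs, file, channel_names = NULL,
                      physical_dim = "uV") {
  data <- as.matrix(data)
  ns <- nrow(data)
  if (fs != round(fs)) stop("fs must be an integer for EDF export")
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(ns))
  spr <- as.integer(fs)                       # samples per record
  n_rec <- floor(ncol(data) / spr)
  if (n_rec < 1L) stop("recording shorter than one data record")
  data <- data[, seq_len(n_rec * spr), drop = FALSE]
  # symmetric physical range, encoded in <= 8 ASCII chars; the parsed-back
  # header value is used for scaling so writer and reader agree exactly
  fmt8 <- function(v) {
    s <- sprintf("%.6g", abs(v))
    if (nchar(s) > 7L) s <- sprintf("%.1e", abs(v))
    if (v < 0) s <- paste0("-", s)
    s
  }
  amp <- max(abs(range(data)), 1e-6)
  pmax_ <- as.numeric(fmt8(amp * 1.001))
  while (pmax_ < amp) pmax_ <- as.numeric(fmt8(pmax_ * 1.01))
  pmin_ <- -pmax_
  dmin <- -32768L; dmax <- 32767L
  pad <- function(x, w) {
    s <- formatC(as.character(x), width = w, flag = "-")
    substr(s, 1L, w)
  }
  con <- file(file, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad("0", 8), pad("synthetic", 80), pad("synthetic", 80),
    pad("01.01.00", 8), pad("00.00.00", 8),
    pad(256 + ns * 256, 8), pad("", 44),
    pad(n_rec, 8), pad(1, 8), pad(ns, 8)
  )
  writeChar(hdr, con, eos = NULL)
  fields <- c(
    vapply(channel_names, pad, character(1), w = 16),
    rep(pad("", 80), ns),                      # transducer
    rep(pad(physical_dim, 8), ns),
    rep(pad(fmt8(pmin_), 8), ns),
    rep(pad(fmt8(pmax_), 8), ns),
    rep(pad(dmin, 8), ns),
    rep(pad(dmax, 8), ns),
    rep(pad("", 80), ns),                      # prefiltering
    rep(pad(spr, 8), ns),
    rep(pad("", 32), ns)
  )
  writeChar(paste(fields, collapse = ""), con, eos = NULL)
  gain <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      seg <- data[ch, ((r - 1L) * spr + 1L):(r * spr)]
      dig <- as.integer(round((seg - pmin_) * gain) + dmin)
      writeBin(dig, con, size = 2L, endian = "little")
    }
  }
  invisible(file)
}

#' Read an EDF file written by [write_edf()] (or any plain 16-bit EDF)
#'
#' @param file EDF path.
#' @return list with `data` (channels x samples, physical units), `fs`,
#'   `channel_names`, `physical_dim`.
#' @export
read_edf <- function(file) {
  con <- file(file, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                        # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(8))
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)
  dims <- vapply(seq_len(ns), function(i) rd(8), character(1))
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(32)
  out <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", spr[ch], size = 2L, signed = TRUE,
                     endian = "little")
      phys <- (dig - dmin[ch]) * (pmax_[ch] - pmin_[ch]) /
        (dmax[ch] - dmin[ch]) + pmin_[ch]
      out[ch, ((r - 1L) * spr[ch] + 1L):(r * spr[ch])] <- phys
    }
  }
  list(data = out, fs = spr[1] / rec_dur, channel_names = labels,
       physical_dim = dims[1])
}

#' Read an EEG/ECG recording from disk
#'
#' Dispatches on extension: `.edf` via [read_edf()], otherwise a
#' delimited matrix (rows = channels, tab-separated, optional header of
#' channel names) read with an `fs` you supply.
#'
#' @param file path to an EDF or delimited matrix file.
#' @param fs sampling rate, required for delimited input.
#' @param modality `"eeg"` or `"ecg"`.
#' @return an `emorec_eeg` or `emorec_ecg` object.
#' @export
read_recording <- function(file, fs = NULL, modality = c("eeg", "ecg")) {
  modality <- match.arg(modality)
  if (grepl("\\.edf$", file, ignore.case = TRUE)) {
    e <- read_edf(file)
    dat <- e$data; fs <- e$fs; chn <- e$channel_names
  } else {
    if (is.null(fs)) stop("fs is required for delimited input")
    dat <- as.matrix(utils::read.table(file, sep = "\t", header = FALSE))
    chn <- paste0("ch", seq_len(nrow(dat)))
  }
  if (modality == "eeg") {
    eeg_recording(dat, fs, chn)
  } else {
    structure(list(data = as.numeric(dat[1, ]), fs = fs, meta = list()),
              class = "emorec_ecg")
  }
}
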