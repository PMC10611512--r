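#' EEG recording container
#'
#' @param data channels x samples numeric matrix (uV).
#' @param fs sampling rate (Hz).
#' @param channel_names channel labels, one per row of `data`.
#' @param meta free-form metadata list (emotion, subject, trial, ...).
#' @return object of class `emorec_eeg`.
#' @export
eeg_recording <- function(data, fs, channel_names = NULL, meta = list()) {
  data <- as.matrix(data)
  if (is.null(channel_names)) {
    channel_names <- paste0("ch", seq_len(nrow(data)))
  }
  if (length(channel_names) != nrow(data)) {
    stop("channel count does not match channel_names")
  }
  rownames(data) <- channel_names
  structure(list(data = data, fs = fs, channel_names = channel_names,
                 meta = meta),
            class = "emorec_eeg")
}

#' @export
print.emorec_eeg <- function(x, ...) {
  cat(sprintf("EEG recording: %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

#' The 60-channel recording montage
#'
#' Channel labels of the 60-electrode 10-10 montage used for recording.
#'
#' @return character vector of 60 labels.
#' @export
standard_channel_names <- function() {
  c("FP1", "FPZ", "FP2", "AF3", "AF4", "F7", "F5", "F3", "F1", "FZ",
    "F2", "F4", "F6", "F8", "FT7", "FC5", "FC3", "FC1", "FCZ", "FC2",
    "FC4", "FC6", "FT8", "T7", "T5", "C3", "C1", "CZ", "C2", "C4",
    "T6", "T8", "TP7", "CP5", "CP3", "CP1", "CPZ", "CP2", "CP4", "CP6",
    "TP8", "P7", "P5", "P3", "P1", "PZ", "P2", "P4", "P6", "P8",
    "PO7", "PO5", "PO3", "POZ", "PO2", "PO4", "PO6", "O1", "OZ", "O2")
}

#' Schematic 2-D scalp layout for the montage
#'
#' Schematic (not anatomically projected) scalp-plane coordinates for the
#' 60-channel montage: y runs anterior (+) to posterior (-) by electrode
#' row, x runs left (-) to right (+) by electrode number (odd = left,
#' even = right, Z = midline). Sufficient for per-channel topographic
#' regulation maps; no interpolated heatmaps are produced.
#'
#' @param channels channel labels to lay out.
#' @return data.frame with columns `channel`, `x`, `y`.
#' @export
channel_layout <- function(channels = standard_channel_names()) {
  rows <- c(FP = 4.5, AF = 3.5, F = 2.5, FT = 1.5, FC = 1.5, T = 0,
            C = 0, TP = -1.5, CP = -1.5, P = -2.5, PO = -3.5, O = -4.5)
  parse_one <- function(ch) {
    m <- regmatches(ch, regexec("^([A-Z]+?)(Z|[0-9]+)$", ch))[[1]]
    if (length(m) != 3L) stop("unknown channel: ", ch)
    prefix <- m[2]
    if (!prefix %in% names(rows)) stop("unknown channel: ", ch)
    num <- m[3]
    x <- if (num == "Z") 0
         else {
           k <- as.integer(num)
           if (k %% 2L == 1L) -(k + 1) / 2 else k / 2
         }
    # lateral T5/T6 sit on the parietal row in this montage
    y <- if (ch %in% c("T5", "T6")) -2.5 else rows[[prefix]]
    c(x = x, y = y)
  }
  xy <- t(vapply(toupper(channels), parse_one, numeric(2)))
  data.frame(channel = channels, x = xy[, 1], y = xy[, 2],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Preprocess a raw EEG recording
#'
#' Zero-phase 4th-order Butterworth band-pass 0.3-50 Hz, 50 Hz notch
#' (band-stop, quality factor 30), then decimation to 200 Hz. The 50 Hz
#' band-pass ceiling is below the 100 Hz post-decimation Nyquist, so
#' decimation reduces to exact subsampling. An artifact-removal hook can
#' be supplied: it receives and must return a channels x samples matrix of
#' identical shape (identity by default; a real ICA cleaner can be plugged
#' in for recorded data).
#'
#' @param raw an `emorec_eeg` recording with `fs >= 200`.
#' @param fs_out output rate (default 200 Hz; must divide `fs`).
#' @param bp band-pass edges in Hz.
#' @param notch_freq,notch_q powerline notch centre frequency and quality
#'   factor.
#' @param artifact_hook function(matrix) -> matrix applied after
#'   filtering, before decimation.
#' @return preprocessed `emorec_eeg` at `fs_out`.
#' @export
preprocess_eeg <- function(raw, fs_out = 200, bp = c(0.3, 50),
                           notch_freq = 50, notch_q = 30,
                           artifact_hook = identity) {
  if (raw$fs < 200) stop("sampling rate must be at least 200 Hz")
  if (raw$fs %% fs_out != 0) stop("fs must be a multiple of fs_out")
  bpf <- design_butter(4, bp[1], bp[2], raw$fs)
  bw <- notch_freq / notch_q
  ntf <- design_butter(2, notch_freq - bw / 2, notch_freq + bw / 2,
                       raw$fs, type = "stop")
  y <- filtfilt_mat(bpf, t(raw$data))
  y <- filtfilt_mat(ntf, y)
  y <- t(y)
  y <- artifact_hook(y)
  if (!identical(dim(y), dim(raw$data))) {
    stop("artifact_hook must preserve the data shape")
  }
  dec <- raw$fs / fs_out
  y <- y[, seq(1L, ncol(y), by = dec), drop = FALSE]
  eeg_recording(y, fs_out, raw$channel_names,
                meta = c(raw$meta, list(preprocessed = TRUE)))
}

#' Cut a recording into non-overlapping fixed-length epochs
#'
#' Contiguous non-overlapping epochs of `length_s` seconds; the trailing
#' remainder is dropped.
#'
#' @param rec an `emorec_eeg` recording.
#' @param length_s epoch length in seconds (default 1).
#' @return 3-D array `[epoch, channel, sample]` (possibly zero epochs).
#' @export
epoch_eeg <- function(rec, length_s = 1) {
  len <- round(length_s * rec$fs)
  n_ep <- floor(ncol(rec$data) / len)
  out <- array(0, dim = c(n_ep, nrow(rec$data), len),
               dimnames = list(NULL, rec$channel_names, NULL))
  for (e in seq_len(n_ep)) {
    out[e, , ] <- rec$data[, ((e - 1L) * len + 1L):(e * len)]
  }
  out
}

#' Differential entropy of a signal segment
#'
#' Closed-form differential entropy of a Gaussian variable,
#' `0.5 * log(2 * pi * e * s^2)` in nats, with `s^2` the unbiased sample
#' variance of the segment. A zero-variance segment returns `-Inf` with a
#' warning (flagged invalid downstream).
#'
#' @param segment numeric vector, length >= 2.
#' @return differential entropy in nats.
#' @examples
#' differential_entropy(rnorm(10000)) # ~ 0.5 * log(2 * pi * exp(1))
#' @export
differential_entropy <- function(segment) {
  if (length(segment) < 2L) stop("segment must have length >= 2")
  s2 <- stats::var(segment)
  if (s2 <= 0) {
    warning("zero-variance segment: differential entropy is -Inf")
    return(-Inf)
  }
  0.5 * log(2 * pi * exp(1) * s2)
}

#' Extract per-epoch differential-entropy band features
#'
#' Cuts the preprocessed recording into 1-s epochs, band-passes every
#' epoch of every channel into each of the five bands (zero-phase
#' 4th-order Butterworth with reflective padding), and computes the
#' Gaussian differential entropy of each band-limited segment. Columns
#' are ordered channel-major, band-minor (`<channel>.<band>`), giving
#' 60 channels x 5 bands = 300 columns on the full montage.
#'
#' @param rec a preprocessed `emorec_eeg` recording.
#' @param bands band definition table.
#' @param epoch_s epoch length in seconds.
#' @return object of class `emorec_features`: list with `features`
#'   (n_epochs x n_channels*n_bands matrix, nats), `labels` (data.frame
#'   with epoch index + recording metadata), `channels`, `bands`.
#' @export
extract_de_features <- function(rec, bands = eeg_bands(), epoch_s = 1) {
  ep <- epoch_eeg(rec, epoch_s)
  n_ep <- dim(ep)[1]
  nch <- dim(ep)[2]
  len <- dim(ep)[3]
  nb <- nrow(bands)
  feat <- matrix(NA_real_, n_ep, nch * nb)
  if (n_ep > 0L) {
    # samples x (epoch*channel) matrix: filter all segments of a band at once
    segs <- matrix(aperm(ep, c(3L, 1L, 2L)), nrow = len)
    for (b in seq_len(nb)) {
      flt <- design_butter(4, bands$lo[b], bands$hi[b], rec$fs)
      y <- filtfilt_mat(flt, segs)
      v <- colSums((y - matrix(colMeans(y), len, ncol(y),
                               byrow = TRUE))^2) / (len - 1)
      de <- ifelse(v > 0, 0.5 * log(2 * pi * exp(1) * v), -Inf)
      # column j of segs is (epoch e, channel c) with e fastest
      feat[, (seq_len(nch) - 1L) * nb + b] <- matrix(de, n_ep, nch)
    }
    if (any(!is.finite(feat))) {
      warning("non-finite differential entropy in ",
              sum(!is.finite(feat)), " cells (zero-variance segments)")
    }
  }
  colnames(feat) <- paste(rep(rec$channel_names, each = nb),
                          rep(bands$name, nch), sep = ".")
  labels <- data.frame(epoch = seq_len(n_ep))
  for (f in c("subject", "session", "trial", "emotion")) {
    if (!is.null(rec$meta[[f]])) labels[[f]] <- rec$meta[[f]]
  }
  structure(list(features = feat, labels = labels,
                 channels = rec$channel_names, bands = bands),
            class = "emorec_features")
}

#' @export
print.emorec_features <- function(x, ...) {
  cat(sprintf("Feature set: %d epochs x %d features (%d channels x %d bands)\n",
              nrow(x$features), ncol(x$features), length(x$channels),
              nrow(x$bands)))
  invisible(x)
}

#' Write a feature table as delimited text
#'
#' Tab-separated table: label columns first, then one column per
#' (channel, band) feature.
#'
#' @param x an `emorec_features` object.
#' @param file output path.
#' @export
write_features <- function(x, file) {
  utils::write.table(cbind(x$labels, as.data.frame(x$features)), file,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
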