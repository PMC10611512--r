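#' Preprocess a raw ECG recording
#'
#' Zero-phase 4th-order Butterworth band-pass 0.4-10 Hz (removes baseline
#' drift/DC and high-frequency muscle noise), then decimation to 200 Hz
#' (exact subsampling: the 10 Hz ceiling is far below the new Nyquist).
#'
#' @param raw an `emorec_ecg` recording with `fs >= 200`.
#' @param fs_out output rate (must divide `fs`).
#' @param bp band-pass edges in Hz.
#' @return preprocessed `emorec_ecg` at `fs_out`.
#' @export
preprocess_ecg <- function(raw, fs_out = 200, bp = c(0.4, 10)) {
  if (raw$fs < 200) stop("sampling rate must be at least 200 Hz")
  if (raw$fs %% fs_out != 0) stop("fs must be a multiple of fs_out")
  # anti-alias with the 10 Hz low-pass at the raw rate, subsample, then
  # band-pass at 200 Hz: the full band-pass realized at the raw rate has
  # normalized cutoffs so small that its pole radii exceed 1 after
  # coefficient rounding (numerically unstable)
  y <- raw$data
  if (raw$fs > fs_out) {
    lp <- design_butter(4, bp[2], NULL, raw$fs, type = "low")
    y <- filtfilt_vec(lp, y)
    y <- y[seq(1L, length(y), by = raw$fs / fs_out)]
  }
  flt <- design_butter(4, bp[1], bp[2], fs_out)
  y <- filtfilt_vec(flt, y)
  out <- raw
  out$data <- y
  out$fs <- fs_out
  out$meta <- c(raw$meta, list(preprocessed = TRUE))
  out
}

#' RR-interval series
#'
#' @param peak_times R-peak times in seconds (increasing).
#' @param clean drop intervals outside `rr_limits` (with their count
#'   recorded in attribute `n_dropped`).
#' @param rr_limits physiological interval bounds in seconds.
#' @return object of class `emorec_rr`: list with `peak_times`,
#'   `intervals` (s), `n_dropped`.
#' @export
rr_series <- function(peak_times, clean = TRUE, rr_limits = c(0.2, 3)) {
  peak_times <- sort(as.numeric(peak_times))
  iv <- diff(peak_times)
  n_dropped <- 0L
  if (clean && length(iv)) {
    bad <- iv < rr_limits[1] | iv > rr_limits[2]
    n_dropped <- sum(bad)
    iv <- iv[!bad]
  }
  structure(list(peak_times = peak_times, intervals = iv,
                 n_dropped = n_dropped),
            class = "emorec_rr")
}

#' @export
print.emorec_rr <- function(x, ...) {
  cat(sprintf("RR series: %d intervals, mean %.3f s (%d dropped in cleaning)\n",
              length(x$intervals), mean(x$intervals), x$n_dropped))
  invisible(x)
}

#' Detect R peaks in a preprocessed ECG
#'
#' Energy-based detector in the derivative-square-integrate family:
#' differentiate the band-passed signal, square, smooth with a 150 ms
#' moving average, threshold adaptively per 10-s chunk (a fraction of the
#' chunk's peak energy), and enforce a 250 ms refractory period; each
#' detection is then refined to the local maximum of the filtered signal.
#'
#' @param rec a preprocessed `emorec_ecg`.
#' @param refractory minimum peak spacing (s).
#' @param threshold_frac energy threshold as a fraction of the chunk peak
#'   energy.
#' @return an `emorec_rr` series (peak times in seconds).
#' @export
detect_r_peaks <- function(rec, refractory = 0.25, threshold_frac = 0.25) {
  fs <- rec$fs
  x <- rec$data
  n <- length(x)
  d <- c(0, diff(x)) * fs
  e <- d^2
  w <- max(3L, round(0.15 * fs))
  kern <- rep(1 / w, w)
  integ <- as.numeric(stats::filter(e, kern, sides = 2))
  integ[is.na(integ)] <- 0
  # adaptive threshold per 10-s chunk
  chunk <- pmin(ceiling(seq_len(n) / (10 * fs)), ceiling(n / (10 * fs)))
  thr <- stats::ave(integ, chunk, FUN = function(v) {
    m <- max(v)
    if (m <= 0) Inf else threshold_frac * m
  })
  above <- integ > thr
  if (!any(above)) stop("no QRS energy above threshold (flat signal?)")
  # candidate = local maxima of integ among supra-threshold samples
  cand <- which(above &
                  integ >= c(-Inf, integ[-n]) &
                  integ > c(integ[-1], -Inf))
  cand <- cand[order(-integ[cand])]
  keep <- logical(0)
  taken <- integer(0)
  min_gap <- round(refractory * fs)
  for (c0 in cand) {
    if (!length(taken) || all(abs(taken - c0) >= min_gap)) {
      taken <- c(taken, c0)
    }
  }
  taken <- sort(taken)
  # refine to the maximum of the filtered signal near each detection
  half <- round(0.1 * fs)
  peaks <- vapply(taken, function(c0) {
    lo <- max(1L, c0 - half)
    hi <- min(n, c0 + half)
    as.integer(lo + which.max(x[lo:hi]) - 1L)
  }, integer(1))
  peaks <- sort(unique(peaks))
  # merge refinements that collapsed within the refractory window
  if (length(peaks) > 1L) {
    ok <- c(TRUE, diff(peaks) >= min_gap)
    peaks <- peaks[ok]
  }
  if (length(peaks) < 2L) stop("fewer than 2 R peaks detected")
  rr_series((peaks - 1L) / fs)
}

#' Restrict an RR series to a time window
#'
#' @param rr an `emorec_rr`.
#' @param start,end window bounds in seconds (peaks with
#'   `start <= t <= end` are kept).
#' @return an `emorec_rr` for the window, carrying the window span as
#'   attribute `span_s`.
#' @export
window_rr <- function(rr, start, end) {
  keep <- rr$peak_times >= start & rr$peak_times <= end
  out <- rr_series(rr$peak_times[keep])
  attr(out, "span_s") <- end - start
  out
}

#' Time-domain HRV features
#'
#' SDNN uses the population (1/N) variance of the intervals; RMSSD is the
#' root mean square of the N-1 successive differences; SDSD is the
#' population standard deviation of those differences; NN50 counts
#' successive differences whose magnitude exceeds 50 ms; pNN50 is
#' 100 * NN50 / (N - 1).
#'
#' @param rr an `emorec_rr` with at least 2 intervals.
#' @return named list: `sdnn`, `rmssd`, `sdsd` (s), `nn50` (count),
#'   `pnn50` (percent).
#' @examples
#' hrv_time_domain(rr_series(cumsum(c(0, 0.80, 0.86, 0.78))))
#' @export
hrv_time_domain <- function(rr) {
  x <- rr$intervals
  n <- length(x)
  if (n < 2L) stop("need at least 2 RR intervals")
  d <- diff(x)
  nn50 <- sum(abs(d) > 0.05)
  list(
    sdnn = sqrt(mean((x - mean(x))^2)),
    rmssd = sqrt(mean(d^2)),
    sdsd = sqrt(mean((d - mean(d))^2)),
    nn50 = nn50,
    pnn50 = 100 * nn50 / (n - 1)
  )
}

#' Geometric HRV features from the RR histogram
#'
#' The RR histogram uses bins of width `bin_width` (default 1/128 s, the
#' conventional discretization). TRI is the total interval count divided
#' by the modal bin count. TINN is the base width (ms) of the best
#' least-squares triangle fitted to the histogram: the triangle rises
#' linearly from zero at N to the modal height at the modal bin centre
#' and falls to zero at M, with N and M searched over bin-edge positions
#' on either side of the mode.
#'
#' @param rr an `emorec_rr` with at least `min_n` intervals.
#' @param bin_width histogram bin width (s).
#' @param min_n minimum interval count (default 20); fewer returns
#'   NA values with a warning.
#' @return named list: `tri`, `tinn` (ms).
#' @export
hrv_geometric <- function(rr, bin_width = 1 / 128, min_n = 20L) {
  x <- rr$intervals
  if (length(x) < min_n) {
    warning("too few RR intervals for geometric features")
    return(list(tri = NA_real_, tinn = NA_real_))
  }
  ext <- 3L   # empty guard bins so wide triangles pay for their overhang
  lo <- (floor(min(x) / bin_width) - ext) * bin_width
  hi <- (ceiling(max(x) / bin_width + 1e-9) + ext) * bin_width
  breaks <- seq(lo, hi + bin_width / 2, by = bin_width)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  cnt <- h$counts
  ctr <- h$mids
  mode_i <- which.max(cnt)
  tri <- length(x) / cnt[mode_i]
  edges <- seq(lo, hi, by = bin_width)
  X <- ctr[mode_i]
  Y <- cnt[mode_i]
  left_cand <- edges[edges < X]
  right_cand <- edges[edges > X]
  best <- Inf
  best_nm <- c(X - bin_width / 2, X + bin_width / 2)
  for (N in left_cand) {
    tri_left <- ifelse(ctr <= X & ctr >= N, Y * (ctr - N) / (X - N), 0)
    for (M in right_cand) {
      tri_right <- ifelse(ctr > X & ctr <= M, Y * (M - ctr) / (M - X), 0)
      err <- sum((cnt - (tri_left + tri_right))^2)
      if (err < best) {
        best <- err
        best_nm <- c(N, M)
      }
    }
  }
  list(tri = tri, tinn = 1000 * (best_nm[2] - best_nm[1]))
}

#' Frequency-domain HRV features
#'
#' The irregularly sampled tachogram (RR interval against the time of its
#' closing peak) is cubic-spline interpolated onto a uniform 4 Hz grid,
#' demeaned, and its Welch power spectral density integrated
#' (trapezoidal) over the conventional bands: VLF <= 0.04 Hz,
#' LF 0.04-0.15 Hz, HF 0.15-0.4 Hz. LF% and HF% are each band's share of
#' total (VLF+LF+HF) power, x100.
#'
#' @param rr an `emorec_rr`; its peaks must span at least `min_span_s`
#'   seconds, otherwise NA values are returned with a warning. The
#'   default 55 s admits the 60-s analysis windows whose interior peak
#'   span is necessarily slightly shorter than the window.
#' @param fs_interp tachogram resampling rate (Hz).
#' @param min_span_s minimum peak time span (s).
#' @return named list: `vlf`, `lf`, `hf` (s^2), `lf_hf`, `lf_pct`,
#'   `hf_pct`.
#' @export
hrv_frequency_domain <- function(rr, fs_interp = 4, min_span_s = 55) {
  tt <- rr$peak_times[-1]
  span <- attr(rr, "span_s") %||%
    (max(rr$peak_times) - min(rr$peak_times))
  if (span < min_span_s || length(rr$intervals) < 4L) {
    warning("RR span too short for spectral features")
    return(list(vlf = NA_real_, lf = NA_real_, hf = NA_real_,
                lf_hf = NA_real_, lf_pct = NA_real_, hf_pct = NA_real_))
  }
  grid <- seq(min(tt), max(tt), by = 1 / fs_interp)
  tach <- stats::spline(tt, rr$intervals, xout = grid, method = "natural")$y
  tach <- tach - mean(tach)
  ps <- welch_psd(tach, fs_interp, nperseg = min(length(tach), 256L))
  band_power <- function(flo, fhi) {
    sel <- ps$freq > flo & ps$freq <= fhi
    if (sum(sel) < 2L) return(0)
    trapz(ps$freq[sel], ps$psd[sel])
  }
  vlf <- band_power(0, 0.04)
  lf <- band_power(0.04, 0.15)
  hf <- band_power(0.15, 0.4)
  tot <- vlf + lf + hf
  list(
    vlf = vlf, lf = lf, hf = hf,
    lf_hf = if (hf > 0) lf / hf else NA_real_,
    lf_pct = if (tot > 0) 100 * lf / tot else NA_real_,
    hf_pct = if (tot > 0) 100 * hf / tot else NA_real_
  )
}

#' Detrended fluctuation analysis
#'
#' Integrates the mean-centred series, partitions the profile into
#' non-overlapping boxes of each scale `s` (trailing remainder dropped),
#' removes a least-squares line per box, and computes the fluctuation
#' `F(s)` as the root mean square of the detrended profile. `alpha1` is
#' the slope of log F(s) against log s over the short scales, `alpha2`
#' over the long scales (default 4-16 and 16-64 beats, the standard
#' short/long-range convention).
#'
#' @param x numeric series (e.g. RR intervals) or an `emorec_rr`.
#' @param short_scales,long_scales integer box sizes.
#' @return object of class `emorec_dfa`: list with `alpha1`, `alpha2`,
#'   `scales`, `fluctuation` (F(s) per scale).
#' @export
dfa <- function(x, short_scales = 4:16,
                long_scales = unique(round(exp(seq(log(16), log(64),
                                                   length.out = 10))))) {
  if (inherits(x, "emorec_rr")) x <- x$intervals
  n <- length(x)
  scales <- sort(unique(c(short_scales, long_scales)))
  usable <- scales[scales >= 4 & n >= 2 * scales]
  if (length(usable) < 4L) {
    warning("series too short for DFA")
    return(structure(list(alpha1 = NA_real_, alpha2 = NA_real_,
                          scales = integer(), fluctuation = numeric()),
                     class = "emorec_dfa"))
  }
  y <- cumsum(x - mean(x))
  fl <- vapply(usable, function(s) {
    nseg <- floor(n / s)
    used <- nseg * s
    seg <- matrix(y[seq_len(used)], nrow = s)
    tvec <- seq_len(s)
    tc <- tvec - mean(tvec)
    denom <- sum(tc^2)
    means <- colMeans(seg)
    slopes <- colSums(seg * tc) / denom
    resid <- seg - matrix(means, s, nseg, byrow = TRUE) -
      outer(tc, slopes)
    sqrt(mean(resid^2))
  }, numeric(1))
  fit_alpha <- function(sc) {
    sel <- usable %in% sc & fl > 0
    if (sum(sel) < 2L) return(NA_real_)
    unname(stats::coef(stats::lm(log(fl[sel]) ~ log(usable[sel])))[2])
  }
  structure(
    list(alpha1 = fit_alpha(short_scales), alpha2 = fit_alpha(long_scales),
         scales = usable, fluctuation = fl),
    class = "emorec_dfa"
  )
}

#' @export
print.emorec_dfa <- function(x, ...) {
  cat(sprintf("DFA: alpha1 = %.3f (short scales), alpha2 = %.3f (long scales)\n",
              x$alpha1, x$alpha2))
  invisible(x)
}

#' Approximate entropy
#'
#' Regularity statistic `phi_m(r) - phi_{m+1}(r)` over embedded template
#' vectors, using the Chebyshev (maximum componentwise) distance with
#' self-matches included: `C_i^m(r)` is the fraction of templates whose
#' distance to template i is strictly below `r`, and
#' `phi_m(r)` averages `ln C_i^m(r)`.
#'
#' @param x numeric series (length >= m + 2) or an `emorec_rr`.
#' @param m template length (default 2).
#' @param r tolerance (> 0), on the scale of `x`.
#' @return approximate entropy (nats); 0 for a constant series.
#' @examples
#' apen(rep(1, 50), m = 2, r = 0.2) # 0
#' @export
apen <- function(x, m = 2L, r) {
  if (inherits(x, "emorec_rr")) x <- x$intervals
  if (r <= 0) stop("r must be positive")
  n <- length(x)
  if (n < m + 2L) stop("series too short for the chosen m")
  phi <- function(mm) {
    nt <- n - mm + 1L
    emb <- sapply(seq_len(mm), function(k) x[k:(k + nt - 1L)])
    emb <- matrix(emb, nrow = nt)
    cnt <- vapply(seq_len(nt), function(i) {
      dmax <- abs(emb - matrix(emb[i, ], nt, mm, byrow = TRUE))
      if (mm > 1L) dmax <- apply(dmax, 1L, max)
      sum(dmax < r)
    }, numeric(1))
    mean(log(cnt / nt))
  }
  phi(m) - phi(m + 1L)
}

#' Poincare plot descriptors
#'
#' SD1 (short-term, perpendicular to the identity line) and SD2
#' (long-term, along it) of the lagged RR scatter, from the sample
#' variances of the interval series and its successive differences.
#'
#' @param rr an `emorec_rr` with at least 3 intervals.
#' @return named list `sd1`, `sd2` (s).
#' @export
poincare <- function(rr) {
  x <- rr$intervals
  if (length(x) < 3L) stop("need at least 3 RR intervals")
  d <- diff(x)
  sd1 <- sqrt(stats::var(d) / 2)
  sd2sq <- 2 * stats::var(x) - stats::var(d) / 2
  list(sd1 = sd1, sd2 = sqrt(max(0, sd2sq)))
}

#' The 19-feature HRV vector
#'
#' Assembles the full battery in a fixed, documented order:
#' time/geometric `SDNN, RMSSD, SDSD, NN50, pNN50, TRI, TINN`;
#' frequency `VLF, LF, HF, LF_HF, LF_pct, HF_pct`;
#' nonlinear `alpha1, alpha2, ApEn, SD1, SD2`; and `HR` (bpm,
#' 60 / mean RR) — 19 values. The approximate-entropy tolerance defaults
#' to `r_coef` times the standard deviation of the window
#' (`apen_r_mode = "sd"`); a variance-based mode is available for
#' sensitivity analysis.
#'
#' @param rr an `emorec_rr`.
#' @param apen_m,apen_r_mode,r_coef approximate-entropy settings.
#' @param bin_width histogram bin width for the geometric features.
#' @return named numeric vector of length 19.
#' @export
extract_hrv_vector <- function(rr, apen_m = 2L,
                               apen_r_mode = c("sd", "variance"),
                               r_coef = 0.2, bin_width = 1 / 128) {
  apen_r_mode <- match.arg(apen_r_mode)
  x <- rr$intervals
  td <- hrv_time_domain(rr)
  geo <- hrv_geometric(rr, bin_width = bin_width)
  fq <- hrv_frequency_domain(rr)
  df_res <- dfa(rr)
  scale <- if (apen_r_mode == "sd") stats::sd(x) else stats::var(x)
  r <- r_coef * scale
  ap <- if (r > 0 && length(x) >= apen_m + 2L) apen(x, apen_m, r)
        else NA_real_
  pc <- poincare(rr)
  c(
    SDNN = td$sdnn, RMSSD = td$rmssd, SDSD = td$sdsd,
    NN50 = td$nn50, pNN50 = td$pnn50, TRI = geo$tri, TINN = geo$tinn,
    VLF = fq$vlf, LF = fq$lf, HF = fq$hf, LF_HF = fq$lf_hf,
    LF_pct = fq$lf_pct, HF_pct = fq$hf_pct,
    alpha1 = df_res$alpha1, alpha2 = df_res$alpha2, ApEn = ap,
    SD1 = pc$sd1, SD2 = pc$sd2,
    HR = 60 / mean(x)
  )
}

#' Sliding analysis windows over a recording
#'
#' 60-s windows advanced by `window_s - overlap_s` (default 5 s hop),
#' i.e. `floor((T - window_s) / hop) + 1` windows for a T-second
#' recording; a recording shorter than one window yields zero windows
#' with a warning.
#'
#' @param rec an `emorec_eeg` or `emorec_ecg` recording.
#' @param window_s window length (s).
#' @param overlap_s overlap between consecutive windows (s).
#' @return list of `list(start, end)` window bounds in seconds.
#' @export
segment_windows <- function(rec, window_s = 60, overlap_s = 55) {
  dur <- if (is.matrix(rec$data)) ncol(rec$data) / rec$fs
         else length(rec$data) / rec$fs
  hop <- window_s - overlap_s
  if (hop <= 0) stop("overlap must be shorter than the window")
  if (dur < window_s) {
    warning("recording shorter than one window")
    return(list())
  }
  starts <- seq(0, dur - window_s + 1e-9, by = hop)
  lapply(starts, function(s) list(start = s, end = s + window_s))
}
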