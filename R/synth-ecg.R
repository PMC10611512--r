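#' Default per-emotion heart parameters
#'
#' Mean heart rate (bpm), RR variability SDNN (s) and sympathovagal
#' balance LF/HF targets the generator associates with each emotion.
#' Cardiac autonomic reactivity tracks arousal far more than valence:
#' calmness (low arousal) keeps a slow, variable, vagally dominated
#' rhythm, while the four high-arousal emotions raise heart rate and
#' LF/HF and depress SDNN — fear most strongly, sadness least. The
#' three negative profiles therefore straddle the happiness profile
#' (their common mean nearly coincides with it), so shrinking them
#' toward that mean (the `negative_overlap` mechanism) erodes both
#' their mutual separation and their contrast with happiness.
#'
#' @return data.frame with rownames = emotions and columns `mean_hr`,
#'   `sdnn`, `lf_hf`.
#' @export
default_heart_profiles <- function() {
  data.frame(
    mean_hr = c(calmness = 63, happiness = 74, sadness = 70,
                fear = 79, anger = 73),
    sdnn = c(0.052, 0.038, 0.042, 0.032, 0.040),
    lf_hf = c(1.0, 2.5, 1.8, 3.6, 2.2)
  )
}

#' ECG generator parameters
#'
#' @param heart_profiles per-emotion data.frame (`mean_hr` bpm in
#'   \[40, 180\], `sdnn` s > 0, `lf_hf` ratio > 0).
#' @param fs_raw sampling rate (default 1000 Hz).
#' @param qrs_template_width full width of the Gaussian QRS bump in
#'   seconds (default 0.02); the template SD is half of this.
#' @param qrs_amp R-wave amplitude (mV).
#' @param noise_sd additive measurement noise SD (mV).
#' @param white_frac fraction of RR variance assigned to beat-to-beat
#'   white noise; the rest is split between the 0.1 Hz (LF) and 0.25 Hz
#'   (HF) sinusoidal modulations according to `lf_hf`.
#' @param negative_overlap in \[0, 1\]: shrink the low-valence emotions'
#'   heart parameters (mean HR linearly; SDNN and LF/HF on the log scale)
#'   toward their common mean.
#' @param negative_set emotions the shrinkage applies to (default: all
#'   low-valence emotions present in the profile table).
#' @return list of class `emorec_ecg_params`.
#' @export
ecg_gen_params <- function(heart_profiles = default_heart_profiles(),
                           fs_raw = 1000, qrs_template_width = 0.02,
                           qrs_amp = 1, noise_sd = 0.02,
                           white_frac = 0.1,
                           negative_overlap = 0, negative_set = NULL) {
  if (any(heart_profiles$mean_hr < 40 | heart_profiles$mean_hr > 180)) {
    stop("mean_hr must lie in [40, 180] bpm")
  }
  if (any(heart_profiles$sdnn <= 0)) stop("sdnn targets must be positive")
  if (negative_overlap < 0 || negative_overlap > 1) {
    stop("negative_overlap must lie in [0, 1]")
  }
  structure(
    list(heart_profiles = heart_profiles, fs_raw = fs_raw,
         qrs_template_width = qrs_template_width, qrs_amp = qrs_amp,
         noise_sd = noise_sd, white_frac = white_frac,
         negative_overlap = negative_overlap, negative_set = negative_set),
    class = "emorec_ecg_params"
  )
}

#' Effective heart parameters for an emotion
#'
#' Per-emotion heart parameters after the negative-overlap shrinkage:
#' mean HR is shrunk linearly, SDNN and LF/HF on the log scale (keeping
#' them positive), toward the mean over the low-valence emotions in
#' `negative_set`.
#'
#' @param emotion emotion name.
#' @param params `emorec_ecg_params`.
#' @return list with `mean_hr`, `sdnn`, `lf_hf`.
#' @export
expected_heart_params <- function(emotion, params = ecg_gen_params()) {
  hp <- params$heart_profiles
  if (!emotion %in% rownames(hp)) stop("unknown emotion: ", emotion)
  ov <- params$negative_overlap
  neg <- params$negative_set %||% negative_emotions(rownames(hp))
  neg <- intersect(neg, rownames(hp))
  out <- as.list(hp[emotion, c("mean_hr", "sdnn", "lf_hf")])
  if (ov > 0 && length(neg) >= 2L && emotion %in% neg) {
    sub <- hp[neg, ]
    out$mean_hr <- mean(sub$mean_hr) +
      (1 - ov) * (out$mean_hr - mean(sub$mean_hr))
    out$sdnn <- exp(mean(log(sub$sdnn)) +
                      (1 - ov) * (log(out$sdnn) - mean(log(sub$sdnn))))
    out$lf_hf <- exp(mean(log(sub$lf_hf)) +
                       (1 - ov) * (log(out$lf_hf) - mean(log(sub$lf_hf))))
  }
  out
}

#' Generate one synthetic single-lead ECG trial
#'
#' RR intervals follow a mean-reverting-free additive process: the target
#' mean interval (60 / mean HR) plus two sinusoidal modulations at 0.1 Hz
#' (LF) and 0.25 Hz (HF) whose amplitude ratio realizes the LF/HF target,
#' plus beat-to-beat Gaussian noise; total modulation variance equals the
#' SDNN target. The waveform places a Gaussian QRS bump (no P/T waves) at
#' each cumulative RR time over a flat baseline with additive noise.
#' Ground-truth R-peak times are returned for detector validation.
#'
#' @param emotion emotion name.
#' @param duration trial length in seconds (>= 70, so at least one 60-s
#'   analysis window fits with margin).
#' @param params `emorec_ecg_params`.
#' @param seed RNG seed.
#' @param hr_offset additive heart-rate offset in bpm (used by the session
#'   generator for subject/trial variability).
#' @param sdnn_scale,lfhf_scale multiplicative modifiers of the SDNN and
#'   LF/HF targets (session-level trial variability).
#' @param hr_drift_sd stationary SD (bpm) of a slow Ornstein-Uhlenbeck
#'   heart-rate wander (correlation time `hr_drift_tau`): emotional
#'   cardiac responses are not stationary over a trial, so successive
#'   analysis windows differ.
#' @param hr_drift_tau correlation time (s) of the heart-rate wander.
#' @return an `emorec_ecg` recording: list with `data` (numeric vector,
#'   mV), `fs`, `peak_times` (ground truth, s), `rr_truth` (s), `meta`.
#' @export
generate_ecg_trial <- function(emotion, duration = 80,
                               params = ecg_gen_params(), seed = NULL,
                               hr_offset = 0, sdnn_scale = 1,
                               lfhf_scale = 1, hr_drift_sd = 4,
                               hr_drift_tau = 8) {
  if (duration < 70) stop("duration must be at least 70 s")
  hp <- expected_heart_params(emotion, params)
  hr <- min(180, max(40, hp$mean_hr + hr_offset))
  mean_rr <- 60 / hr
  sdnn <- hp$sdnn * sdnn_scale
  ratio <- hp$lf_hf * lfhf_scale
  var_w <- params$white_frac * sdnn^2
  var_osc <- sdnn^2 - var_w
  a_hf <- sqrt(2 * var_osc / (1 + ratio))
  a_lf <- sqrt(ratio) * a_hf
  fs <- params$fs_raw
  with_seed(seed, {
    n_beats <- ceiling(duration / mean_rr * 1.5) + 10L
    wander <- stats::rnorm(1, 0, hr_drift_sd)
    wn <- stats::rnorm(n_beats)
    ph <- stats::runif(2, 0, 2 * pi)
    eps <- stats::rnorm(n_beats, 0, sqrt(var_w))
    t_peak <- numeric(n_beats)
    rr <- numeric(n_beats)
    t_cur <- stats::runif(1, 0, mean_rr)  # random first-beat phase
    for (i in seq_len(n_beats)) {
      t_peak[i] <- t_cur
      hr_t <- min(180, max(40, hr + wander))
      d <- 60 / hr_t +
        a_lf * sin(2 * pi * 0.1 * t_cur + ph[1]) +
        a_hf * sin(2 * pi * 0.25 * t_cur + ph[2]) +
        eps[i]
      d <- min(2.5, max(0.3, d))
      rr[i] <- d
      t_cur <- t_cur + d
      decay <- exp(-d / hr_drift_tau)
      wander <- wander * decay +
        hr_drift_sd * sqrt(1 - decay^2) * wn[i]
    }
    keep <- t_peak < duration
    t_peak <- t_peak[keep]
    n <- round(duration * fs)
    x <- numeric(n)
    sig <- params$qrs_template_width / 2
    half <- ceiling(4 * sig * fs)
    tpl_t <- (-half:half) / fs
    tpl <- params$qrs_amp * exp(-tpl_t^2 / (2 * sig^2))
    for (tp in t_peak) {
      c0 <- round(tp * fs) + 1L
      lo <- max(1L, c0 - half)
      hi <- min(n, c0 + half)
      x[lo:hi] <- x[lo:hi] + tpl[(lo - c0 + half + 1L):(hi - c0 + half + 1L)]
    }
    if (params$noise_sd > 0) x <- x + stats::rnorm(n, 0, params$noise_sd)
    structure(
      list(data = x, fs = fs, peak_times = t_peak,
           rr_truth = diff(t_peak),
           meta = list(emotion = emotion, duration = duration, seed = seed,
                       mean_hr = hr, sdnn_target = sdnn,
                       lf_hf_target = ratio)),
      class = "emorec_ecg"
    )
  })
}

#' @export
print.emorec_ecg <- function(x, ...) {
  cat(sprintf("ECG recording: %d samples @ %g Hz (%.1f s)",
              length(x$data), x$fs, length(x$data) / x$fs))
  if (!is.null(x$peak_times)) {
    cat(sprintf(", %d ground-truth R peaks", length(x$peak_times)))
  }
  cat("\n")
  invisible(x)
}
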