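#' Canonical EEG frequency bands
#'
#' Five-band convention used throughout: delta 1-4, theta 4-8, alpha 8-13,
#' beta 13-30, gamma 30-50 Hz. Band edges are configurable wherever bands
#' are consumed.
#'
#' @return data.frame with columns `name`, `lo`, `hi` (Hz).
#' @export
eeg_bands <- function() {
  data.frame(
    name = c("delta", "theta", "alpha", "beta", "gamma"),
    lo = c(1, 4, 8, 13, 30),
    hi = c(4, 8, 13, 30, 50),
    stringsAsFactors = FALSE
  )
}

#' Default per-emotion EEG band-power profiles
#'
#' Multiplicative band-power profiles (rows = emotions, columns = the five
#' bands) encoding the spectral signatures the generator gives each
#' emotion: calmness is alpha-dominant with suppressed beta/gamma;
#' happiness carries elevated beta/gamma; sadness is theta/alpha heavy;
#' fear is beta/gamma heavy with suppressed alpha and theta; anger sits
#' between, with elevated delta. The three negative profiles deliberately
#' straddle the positive ones so that shrinking them toward their common
#' mean (the `negative_overlap` mechanism) erodes both their mutual
#' separation and their contrast against the positive group: in theta,
#' alpha and beta the log-contrast between the negative-group mean and
#' the positive-group mean falls strictly as sadness and then anger join
#' fear (|ln(mean of 1 negative) - ln g| > |.. 2 negatives ..| >
#' |.. 3 negatives ..| against the positive geometric mean g), which is
#' what makes the volcano points in those bands collapse across session
#' designs.
#'
#' @return 5 x 5 numeric matrix with emotion rownames and band colnames.
#' @export
default_band_profiles <- function() {
  m <- rbind(
    calmness  = c(1.0, 1.10, 1.60, 0.80, 0.6),
    happiness = c(1.0, 1.20, 1.00, 1.50, 1.3),
    sadness   = c(1.2, 1.74, 1.23, 1.12, 0.7),
    fear      = c(1.3, 0.90, 0.80, 1.40, 1.6),
    anger     = c(1.4, 0.87, 1.58, 0.87, 1.0)
  )
  colnames(m) <- eeg_bands()$name
  m
}

#' EEG generator parameters
#'
#' @param n_channels number of channels (default 60, the full montage).
#' @param fs_raw raw sampling rate in Hz (default 1000).
#' @param base_power baseline per-band signal power in uV^2 (default 10);
#'   each band's variance is `base_power` times its profile multiplier.
#' @param band_power_profile emotions x 5 bands multiplier matrix.
#' @param negative_overlap in \[0, 1\]: 0 leaves profiles untouched, 1
#'   collapses all low-valence emotion profiles onto their common mean.
#' @param negative_set which emotions the overlap shrinkage applies to
#'   (default: all low-valence emotions present in the profile matrix);
#'   session-level code restricts this to the emotions actually present.
#' @param noise_sd broadband measurement noise SD in uV (default 1).
#' @param channel_gain optional channels x bands matrix of multiplicative
#'   band-power gains (spatial variability; the session generator fills
#'   this with per-trial lognormal draws).
#' @param epoch_jitter_sd SD (log scale) of the second-by-second band-power
#'   modulation shared across channels (default 0.4), emulating the
#'   fluctuating intensity of an emotional state over a trial.
#' @param bands band definition table (`eeg_bands()`).
#' @return list of class `emorec_eeg_params`.
#' @export
eeg_gen_params <- function(n_channels = 60L, fs_raw = 1000,
                           base_power = 10,
                           band_power_profile = default_band_profiles(),
                           negative_overlap = 0,
                           negative_set = NULL,
                           noise_sd = 1,
                           epoch_jitter_sd = 0.4,
                           channel_gain = NULL,
                           bands = eeg_bands()) {
  if (negative_overlap < 0 || negative_overlap > 1) {
    stop("negative_overlap must lie in [0, 1]")
  }
  structure(
    list(n_channels = as.integer(n_channels), fs_raw = fs_raw,
         base_power = base_power, band_power_profile = band_power_profile,
         negative_overlap = negative_overlap, negative_set = negative_set,
         noise_sd = noise_sd, epoch_jitter_sd = epoch_jitter_sd,
         channel_gain = channel_gain, bands = bands),
    class = "emorec_eeg_params"
  )
}

# Shrink the negative-emotion rows of a profile matrix toward their common
# mean by `overlap` (0 = untouched, 1 = fully collapsed).
shrink_profiles <- function(profile, overlap, negative_set = NULL) {
  neg <- negative_set %||% negative_emotions(rownames(profile))
  neg <- intersect(neg, rownames(profile))
  if (length(neg) < 2L || overlap == 0) return(profile)
  m <- colMeans(profile[neg, , drop = FALSE])
  for (e in neg) {
    profile[e, ] <- m + (1 - overlap) * (profile[e, ] - m)
  }
  profile
}

#' Expected band-power vector for an emotion
#'
#' The per-band signal variance (uV^2) the generator targets for a given
#' emotion after applying the negative-overlap shrinkage; broadband noise
#' excluded.
#'
#' @param emotion emotion name.
#' @param params `emorec_eeg_params`.
#' @return named numeric vector (one value per band).
#' @export
expected_band_power <- function(emotion, params = eeg_gen_params()) {
  prof <- shrink_profiles(params$band_power_profile,
                          params$negative_overlap, params$negative_set)
  if (!emotion %in% rownames(prof)) stop("unknown emotion: ", emotion)
  params$base_power * prof[emotion, ]
}

#' Generate one synthetic multichannel EEG trial
#'
#' Each channel is a sum over the five canonical bands of band-limited
#' Gaussian noise whose variance is set by the emotion's (possibly
#' overlap-shrunk) band-power profile, modulated second-by-second by a
#' lognormal gain shared across channels, plus independent broadband
#' noise. Deterministic given `seed`.
#'
#' @param emotion emotion name.
#' @param duration trial length in seconds (>= 2).
#' @param params `emorec_eeg_params`.
#' @param seed RNG seed.
#' @param channel_names optional channel labels (defaults to the standard
#'   montage truncated/recycled to `n_channels`).
#' @return an `emorec_eeg` recording: list with `data` (channels x
#'   samples matrix, uV), `fs`, `channel_names`, `meta`.
#' @export
generate_eeg_trial <- function(emotion, duration = 60,
                               params = eeg_gen_params(), seed = NULL,
                               channel_names = NULL) {
  if (duration < 2) stop("duration must be at least 2 s")
  power <- expected_band_power(emotion, params)   # errors on unknown emotion
  fs <- params$fs_raw
  n <- round(duration * fs)
  nch <- params$n_channels
  if (is.null(channel_names)) {
    full <- standard_channel_names()
    channel_names <- full[((seq_len(nch) - 1L) %% length(full)) + 1L]
  }
  bands <- params$bands
  n_sec <- ceiling(duration)
  sec_of <- pmin(n_sec, floor((seq_len(n) - 1) / fs) + 1L)
  freqs <- (seq_len(n) - 1L) * fs / n
  with_seed(seed, {
    x <- matrix(0, nch, n)
    for (b in seq_len(nrow(bands))) {
      # exact band-limited Gaussian noise by spectral synthesis: complex
      # Gaussian coefficients on the band's positive-frequency bins,
      # Hermitian-symmetrized, inverse FFT
      bins <- which(freqs > bands$lo[b] & freqs <= bands$hi[b] &
                      freqs < fs / 2)
      co <- matrix(complex(real = stats::rnorm(length(bins) * nch),
                           imaginary = stats::rnorm(length(bins) * nch)),
                   length(bins), nch)
      g <- exp(stats::rnorm(n_sec, 0, params$epoch_jitter_sd) -
                 params$epoch_jitter_sd^2 / 2)
      if (power[b] > 0) {
        S <- matrix(0i, n, nch)
        S[bins, ] <- co
        S[n - bins + 2L, ] <- Conj(co)
        bl <- Re(stats::mvfft(S, inverse = TRUE)) / n
        sdv <- apply(bl, 2L, stats::sd)
        sdv[sdv == 0] <- 1
        cg <- if (is.null(params$channel_gain)) rep(1, nch)
              else params$channel_gain[, b]
        bl <- sweep(bl, 2L, sdv / sqrt(cg), "/")
        # per-second lognormal power gain, mean 1, shared across channels
        amp <- sqrt(power[b] * g[sec_of])
        x <- x + t(bl * amp)
      }
    }
    if (params$noise_sd > 0) {
      x <- x + matrix(stats::rnorm(nch * n, 0, params$noise_sd), nch, n)
    }
    eeg_recording(x, fs, channel_names,
                  meta = list(emotion = emotion, duration = duration,
                              seed = seed))
  })
}
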