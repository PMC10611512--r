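#' Generate a full synthetic recording session
#'
#' Produces one raw EEG and one raw ECG trial per (subject, emotion,
#' trial index) for a session design, with subject- and trial-level
#' variability layered on top of the per-emotion generator profiles:
#'
#' * EEG: each subject carries a multiplicative lognormal band-profile
#'   jitter (SD 0.1 on the log scale); each trial additionally carries a
#'   lognormal per-band gain (SD `trial_jitter_sd`, shared across
#'   channels) and an independent per-channel, per-band gain
#'   (SD `trial_channel_sd`) capturing spatial variability of the
#'   response from trial to trial.
#' * ECG: each subject carries an additive heart-rate offset
#'   (SD `subject_hr_sd` bpm); each trial an additional offset
#'   (SD `trial_hr_sd` bpm) plus multiplicative lognormal jitter on the
#'   SDNN and LF/HF targets (SD `trial_sdnn_sd`, `trial_lfhf_sd` on the
#'   log scale).
#'
#' The `negative_overlap` in `eeg_params`/`ecg_params` is applied with the
#' negative set restricted to the low-valence emotions actually present in
#' the session design, so a session containing a single negative emotion
#' is unaffected by the overlap. Fully reproducible given `seed`: the same
#' per-trial sub-seeds are used by [simulate_session_features()].
#'
#' @param design an `emorec_design`.
#' @param eeg_params,ecg_params generator parameter objects.
#' @param seed master RNG seed.
#' @param eeg_duration,ecg_duration trial lengths in seconds.
#' @param subject_profile_sd,trial_jitter_sd lognormal SDs of the EEG
#'   subject/trial band-profile jitter.
#' @param trial_channel_sd lognormal SD of the per-trial, per-channel
#'   band-gain jitter.
#' @param subject_hr_sd,trial_hr_sd SDs (bpm) of the ECG subject/trial
#'   heart-rate offsets.
#' @param trial_sdnn_sd,trial_lfhf_sd lognormal SDs of the per-trial SDNN
#'   and LF/HF jitter.
#' @return object of class `emorec_session`: list with `design`, `trials`
#'   (data.frame subject/emotion/trial/seed), `eeg` and `ecg` (lists of
#'   recordings aligned with `trials` rows), and the parameter objects.
#' @export
generate_session <- function(design, eeg_params = eeg_gen_params(),
                             ecg_params = ecg_gen_params(), seed = 1,
                             eeg_duration = 60, ecg_duration = 80,
                             subject_profile_sd = 0.1,
                             trial_jitter_sd = 0.1, trial_channel_sd = 0.1,
                             subject_hr_sd = 3, trial_hr_sd = 0.5,
                             trial_sdnn_sd = 0.05, trial_lfhf_sd = 0.1) {
  plan <- session_plan(design, seed)
  eeg <- vector("list", nrow(plan))
  ecg <- vector("list", nrow(plan))
  for (k in seq_len(nrow(plan))) {
    tr <- trial_generators(plan[k, ], design, eeg_params, ecg_params,
                           seed, eeg_duration, ecg_duration,
                           subject_profile_sd, trial_jitter_sd,
                           subject_hr_sd, trial_hr_sd,
                           trial_sdnn_sd, trial_lfhf_sd, trial_channel_sd)
    eeg[[k]] <- tr$eeg()
    ecg[[k]] <- tr$ecg()
  }
  structure(
    list(design = design, trials = plan, eeg = eeg, ecg = ecg,
         eeg_params = eeg_params, ecg_params = ecg_params, seed = seed),
    class = "emorec_session"
  )
}

#' @export
print.emorec_session <- function(x, ...) {
  print(x$design)
  cat(sprintf("  %d trial pairs (EEG + ECG)\n", nrow(x$trials)))
  invisible(x)
}

# The (subject, emotion, trial) grid with per-trial sub-seeds.
session_plan <- function(design, seed) {
  plan <- expand.grid(
    trial = seq_len(design$trials_per_emotion),
    emotion = design$emotions,
    subject = seq_len(design$n_subjects),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )[, c("subject", "emotion", "trial")]
  ei <- match(plan$emotion, emotion_labels()$name)
  plan$seed <- mapply(function(s, e, t) derive_seed(seed, s, e, t),
                      plan$subject, ei, plan$trial)
  plan$session <- design$session_id
  plan
}

# Closures generating the raw EEG / ECG recordings for one plan row,
# shared between generate_session() and simulate_session_features().
trial_generators <- function(row, design, eeg_params, ecg_params, seed,
                             eeg_duration, ecg_duration,
                             subject_profile_sd, trial_jitter_sd,
                             subject_hr_sd, trial_hr_sd,
                             trial_sdnn_sd = 0.05, trial_lfhf_sd = 0.1,
                             trial_channel_sd = 0.1) {
  neg <- negative_emotions(design$emotions)
  nb <- nrow(eeg_params$bands)
  # subject-level draws come from a subject-only sub-seed
  subj_draw <- with_seed(derive_seed(seed, row$subject, 0, 0), {
    list(band = exp(stats::rnorm(nb, 0, subject_profile_sd)),
         hr = stats::rnorm(1, 0, subject_hr_sd))
  })
  trial_draw <- with_seed(derive_seed(row$seed, 9L), {
    list(band = exp(stats::rnorm(nb, 0, trial_jitter_sd)),
         chan = matrix(exp(stats::rnorm(eeg_params$n_channels * nb, 0,
                                        trial_channel_sd)),
                       eeg_params$n_channels, nb),
         hr = stats::rnorm(1, 0, trial_hr_sd),
         sdnn = exp(stats::rnorm(1, 0, trial_sdnn_sd)),
         lfhf = exp(stats::rnorm(1, 0, trial_lfhf_sd)))
  })
  ep <- eeg_params
  ep$negative_set <- neg
  gain <- subj_draw$band * trial_draw$band
  ep$band_power_profile <- sweep(ep$band_power_profile, 2L, gain, "*")
  ep$channel_gain <- trial_draw$chan
  cp <- ecg_params
  cp$negative_set <- neg
  meta <- list(subject = row$subject, session = design$session_id,
               trial = row$trial, emotion = row$emotion)
  list(
    eeg = function() {
      r <- generate_eeg_trial(row$emotion, eeg_duration, ep,
                              seed = derive_seed(row$seed, 1L))
      r$meta <- c(meta, r$meta)
      r
    },
    ecg = function() {
      r <- generate_ecg_trial(row$emotion, ecg_duration, cp,
                              seed = derive_seed(row$seed, 2L),
                              hr_offset = subj_draw$hr + trial_draw$hr,
                              sdnn_scale = trial_draw$sdnn,
                              lfhf_scale = trial_draw$lfhf)
      r$meta <- c(meta, r$meta)
      r
    }
  )
}

#' Simulate a session and extract features trial by trial
#'
#' Streaming counterpart of [generate_session()] + the two feature
#' pipelines: each raw trial is generated (same per-trial sub-seeds as
#' `generate_session`, so the signals are identical), pushed through
#' preprocessing and feature extraction, and discarded, keeping memory
#' flat at full scale. EEG trials yield per-epoch differential-entropy
#' vectors; ECG trials yield per-window 19-feature HRV vectors.
#'
#' @inheritParams generate_session
#' @param modalities subset of `c("eeg", "ecg")` to simulate.
#' @param window_s,overlap_s ECG analysis window length and overlap.
#' @return list with elements `eeg` and/or `ecg`, each an
#'   `emorec_dataset`: list(features = matrix, labels = data.frame with
#'   subject, emotion, trial, order) plus the session design.
#' @export
simulate_session_features <- function(design,
                                      eeg_params = eeg_gen_params(),
                                      ecg_params = ecg_gen_params(),
                                      seed = 1,
                                      eeg_duration = 60, ecg_duration = 80,
                                      modalities = c("eeg", "ecg"),
                                      window_s = 60, overlap_s = 55,
                                      subject_profile_sd = 0.1,
                                      trial_jitter_sd = 0.1,
                                      trial_channel_sd = 0.1,
                                      subject_hr_sd = 3, trial_hr_sd = 0.5,
                                      trial_sdnn_sd = 0.05,
                                      trial_lfhf_sd = 0.1) {
  plan <- session_plan(design, seed)
  eeg_feats <- list(); eeg_labs <- list()
  ecg_feats <- list(); ecg_labs <- list()
  for (k in seq_len(nrow(plan))) {
    tr <- trial_generators(plan[k, ], design, eeg_params, ecg_params,
                           seed, eeg_duration, ecg_duration,
                           subject_profile_sd, trial_jitter_sd,
                           subject_hr_sd, trial_hr_sd,
                           trial_sdnn_sd, trial_lfhf_sd, trial_channel_sd)
    if ("eeg" %in% modalities) {
      fs <- extract_de_features(preprocess_eeg(tr$eeg()),
                                bands = eeg_params$bands)
      eeg_feats[[k]] <- fs$features
      eeg_labs[[k]] <- data.frame(
        subject = plan$subject[k], emotion = plan$emotion[k],
        trial = plan$trial[k], order = seq_len(nrow(fs$features))
      )
    }
    if ("ecg" %in% modalities) {
      rec <- preprocess_ecg(tr$ecg())
      rr <- detect_r_peaks(rec)
      wins <- segment_windows(rec, window_s, overlap_s)
      hv <- lapply(wins, function(w) {
        sub <- window_rr(rr, w$start, w$end)
        extract_hrv_vector(sub)
      })
      ecg_feats[[k]] <- do.call(rbind, hv)
      ecg_labs[[k]] <- data.frame(
        subject = plan$subject[k], emotion = plan$emotion[k],
        trial = plan$trial[k], order = seq_along(wins)
      )
    }
  }
  out <- list()
  if ("eeg" %in% modalities) {
    out$eeg <- emorec_dataset(do.call(rbind, eeg_feats),
                              do.call(rbind, eeg_labs), design, "eeg")
  }
  if ("ecg" %in% modalities) {
    out$ecg <- emorec_dataset(do.call(rbind, ecg_feats),
                              do.call(rbind, ecg_labs), design, "ecg")
  }
  out
}

#' Labelled feature dataset for one session
#'
#' @param features samples x features matrix.
#' @param labels data.frame with columns subject, emotion, trial, order.
#' @param design the `emorec_design` the data came from.
#' @param modality "eeg" or "ecg".
#' @return object of class `emorec_dataset`.
#' @export
emorec_dataset <- function(features, labels, design, modality) {
  stopifnot(nrow(features) == nrow(labels))
  bad <- !labels$emotion %in% design$emotions
  if (any(bad)) stop("labels outside the session design")
  structure(list(features = features, labels = labels, design = design,
                 modality = modality),
            class = "emorec_dataset")
}

#' @export
print.emorec_dataset <- function(x, ...) {
  cat(sprintf(
    "%s dataset (session %d): %d samples x %d features, %d subjects, %d classes\n",
    toupper(x$modality), x$design$session_id, nrow(x$features),
    ncol(x$features), length(unique(x$labels$subject)),
    length(unique(x$labels$emotion))
  ))
  invisible(x)
}

#' Write a session to disk
#'
#' One EDF file per trial and modality plus a tab-separated long-format
#' label table (`subject`, `session`, `trial`, `emotion`, `modality`,
#' `file`).
#'
#' @param session an `emorec_session`.
#' @param dir output directory.
#' @return the label table, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (k in seq_len(nrow(session$trials))) {
    tr <- session$trials[k, ]
    for (mod in c("eeg", "ecg")) {
      rec <- session[[mod]][[k]]
      fname <- sprintf("s%02d_subj%02d_%s_t%d_%s.edf", tr$session,
                       tr$subject, tr$emotion, tr$trial, mod)
      dat <- if (mod == "eeg") rec$data else matrix(rec$data, nrow = 1)
      labs <- if (mod == "eeg") rec$channel_names else "ECG"
      write_edf(dat, rec$fs, file.path(dir, fname), channel_names = labs)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = tr$subject, session = tr$session, trial = tr$trial,
        emotion = tr$emotion, modality = mod, file = fname
      )
    }
  }
  tab <- do.call(rbind, rows)
  utils::write.table(tab, file.path(dir, "labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(tab)
}
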