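test_that("rating tables have the requested shape and planted outliers stand out", {
  rt <- generate_ratings(27, 29, outlier_ids = c(4, 11), seed = 7)
  expect_equal(dim(rt$valence), c(27, 29))
  expect_equal(sort(names(rt)),
               sort(c("valence", "arousal", "dominance", "liking",
                      "familiarity")))
  expect_true(all(unlist(rt) %in% 1:5))

  # zero noise, shared latent means: all consistent rows identical
  rt0 <- generate_ratings(3, 5, noise_sd = 0,
                          latent_means = list(valence = c(1, 2, 3, 4, 5),
                                              arousal = rep(3, 5),
                                              dominance = rep(2, 5),
                                              liking = rep(4, 5),
                                              familiarity = rep(5, 5)),
                          seed = 1)
  expect_true(all(rt0$valence[1, ] == rt0$valence[2, ]))
  expect_true(all(rt0$valence[2, ] == rt0$valence[3, ]))

  # the planted annotator has the largest mean distance to the others
  rt1 <- generate_ratings(10, 20, outlier_ids = 1, seed = 1)
  D <- emorec:::rating_distance_matrix(rt1$valence)
  row_means <- vapply(1:10, function(i) mean(D[i, -i]), numeric(1))
  expect_equal(which.max(row_means), 1L)

  expect_error(generate_ratings(27, 1, seed = 1), "invalid design")
  expect_error(generate_ratings(2, 10, seed = 1), "3 annotators")
})

test_that("EEG trials realize the configured band powers", {
  p <- eeg_gen_params(n_channels = 3, noise_sd = 0.5, epoch_jitter_sd = 0)
  tr <- generate_eeg_trial("happiness", 60, p, seed = 3)
  expect_equal(dim(tr$data), c(3, 60000))
  target <- sum(expected_band_power("happiness", p)) + p$noise_sd^2
  v <- apply(tr$data, 1, var)
  expect_true(all(abs(v - target) / target < 0.1))

  # zero-power limit: silence
  p0 <- eeg_gen_params(n_channels = 2, base_power = 0, noise_sd = 0)
  tr0 <- generate_eeg_trial("fear", 5, p0, seed = 1)
  expect_true(all(tr0$data == 0))

  expect_error(generate_eeg_trial("boredom", 10, p), "unknown emotion")
  expect_error(generate_eeg_trial("fear", 1, p), "at least 2")
})

test_that("negative overlap collapses and monotonically shrinks negative profiles", {
  p1 <- eeg_gen_params(negative_overlap = 1)
  expect_equal(expected_band_power("fear", p1),
               expected_band_power("sadness", p1))
  p0 <- eeg_gen_params(negative_overlap = 0)
  expect_equal(p0$band_power_profile["fear", ],
               emorec:::shrink_profiles(p0$band_power_profile, 0)["fear", ])

  pair_dist <- function(ov) {
    pr <- emorec:::shrink_profiles(default_band_profiles(), ov)
    neg <- negative_emotions(rownames(pr))
    d <- 0
    for (i in seq_along(neg)) for (j in seq_along(neg)) {
      if (i < j) d <- d + sqrt(sum((pr[neg[i], ] - pr[neg[j], ])^2))
    }
    d
  }
  dists <- vapply(c(0, 0.25, 0.5, 0.75, 1), pair_dist, numeric(1))
  expect_true(all(diff(dists) <= 1e-12))
  expect_equal(dists[5], 0)
})

test_that("band-power control tightens with duration", {
  p <- eeg_gen_params(n_channels = 1, noise_sd = 0, epoch_jitter_sd = 0)
  tr <- generate_eeg_trial("calmness", 300, p, seed = 5)
  target <- sum(expected_band_power("calmness", p))
  expect_lt(abs(var(tr$data[1, ]) - target) / target, 0.05)
})

test_that("ECG trials honour their heart-parameter targets", {
  tr <- generate_ecg_trial("calmness", 80, seed = 5, hr_drift_sd = 0)
  expect_equal(length(tr$data), 80000)
  # ~80 beats at 60-65 bpm in 80 s
  expect_true(abs(length(tr$peak_times) - 80) <= 12)

  # degenerate variance: constant RR when all modulation is off
  hp <- default_heart_profiles()
  hp$sdnn[] <- 1e-9
  tr0 <- generate_ecg_trial("fear", 70, ecg_gen_params(hp), seed = 2,
                            hr_drift_sd = 0)
  expect_lt(sd(tr0$rr_truth), 1e-6)

  # LF/HF of the ground-truth RR series via the spectral pipeline
  hp2 <- default_heart_profiles()
  hp2["fear", "lf_hf"] <- 4
  tr2 <- generate_ecg_trial("fear", 300, ecg_gen_params(hp2), seed = 9,
                            hr_drift_sd = 0)
  fq <- hrv_frequency_domain(rr_series(tr2$peak_times))
  expect_gt(fq$lf_hf, 2.5)
  expect_lt(fq$lf_hf, 6)

  expect_error(generate_ecg_trial("fear", 30), "at least 70")
})

test_that("generated SDNN tracks the target", {
  hp <- default_heart_profiles()
  for (s in 1:5) {
    tr <- generate_ecg_trial("happiness", 120, seed = s, hr_drift_sd = 0)
    got <- sqrt(mean((tr$rr_truth - mean(tr$rr_truth))^2))
    expect_lt(abs(got - hp["happiness", "sdnn"]) / hp["happiness", "sdnn"],
              0.25)
  }
})

test_that("sessions have the right size, labels and are reproducible", {
  des <- session_design(1, n_subjects = 2, trials_per_emotion = 2)
  p <- eeg_gen_params(n_channels = 2)
  s1 <- generate_session(des, p, seed = 11, eeg_duration = 2,
                         ecg_duration = 70)
  expect_equal(nrow(s1$trials), 2 * 3 * 2)
  expect_equal(length(s1$eeg), nrow(s1$trials))

  des3 <- session_design(3, n_subjects = 1, trials_per_emotion = 1)
  s3 <- generate_session(des3, p, seed = 4, eeg_duration = 2,
                         ecg_duration = 70)
  expect_equal(sort(unique(s3$trials$emotion)),
               sort(c("calmness", "fear", "happiness", "sadness", "anger")))

  s1b <- generate_session(des, p, seed = 11, eeg_duration = 2,
                          ecg_duration = 70)
  expect_identical(s1$eeg[[3]]$data, s1b$eeg[[3]]$data)
  expect_identical(s1$ecg[[5]]$data, s1b$ecg[[5]]$data)
})

test_that("streaming feature simulation matches the materialized session", {
  des <- session_design(1, n_subjects = 1, trials_per_emotion = 1)
  p <- eeg_gen_params(n_channels = 2)
  raw <- generate_session(des, p, seed = 21, eeg_duration = 3,
                          ecg_duration = 70)
  str <- simulate_session_features(des, p, seed = 21, eeg_duration = 3,
                                   ecg_duration = 70, modalities = "eeg")
  k <- which(raw$trials$emotion == "fear")
  direct <- extract_de_features(preprocess_eeg(raw$eeg[[k]]))
  rows <- str$eeg$labels$emotion == "fear"
  expect_equal(unname(str$eeg$features[rows, ]),
               unname(direct$features), tolerance = 1e-12)
})
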