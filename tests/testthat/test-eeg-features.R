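test_that("preprocessing passes the band and rejects out-of-band energy", {
  fs <- 1000
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  mk <- function(f) eeg_recording(matrix(sin(2 * pi * f * t), 1), fs)

  # a 4th-order Butterworth applied forward-backward has gain
  # 1/(1 + (f/50)^8) just above the 50 Hz corner: ~0.19 at 60 Hz,
  # ~0.02 at 80 Hz
  out60 <- preprocess_eeg(mk(60))
  expect_lt(sqrt(mean(out60$data^2)), 0.30 * sqrt(0.5))
  out80 <- preprocess_eeg(mk(80))
  expect_lt(sqrt(mean(out80$data^2)), 0.05 * sqrt(0.5))

  out10 <- preprocess_eeg(mk(10))
  expect_gt(sqrt(mean(out10$data^2)), 0.95 * sqrt(0.5))
  expect_lt(sqrt(mean(out10$data^2)), 1.05 * sqrt(0.5))

  # powerline notch
  out50 <- preprocess_eeg(mk(50))
  expect_lt(sqrt(mean(out50$data^2)), 0.1 * sqrt(0.5))

  # decimation arithmetic and channel order
  expect_equal(ncol(out10$data), 2000)
  expect_equal(out10$fs, 200)
  expect_error(preprocess_eeg(eeg_recording(matrix(0, 1, 100), 100)),
               "at least 200")
})

test_that("the artifact hook contract is enforced", {
  rec <- tiny_eeg(2, 3)
  out <- preprocess_eeg(rec, artifact_hook = function(m) m * 1)
  expect_equal(dim(out$data), c(2, 600))
  expect_error(preprocess_eeg(rec, artifact_hook = function(m) m[1, , drop = FALSE]),
               "shape")
})

test_that("epoching partitions the recording", {
  rec <- eeg_recording(matrix(seq_len(2 * 12140), 2, byrow = FALSE), 200)
  ep <- epoch_eeg(rec)                      # 60.7 s -> 60 epochs
  expect_equal(dim(ep), c(60, 2, 200))
  rec2 <- eeg_recording(matrix(1:100, 1), 200)   # 0.5 s
  expect_equal(dim(epoch_eeg(rec2))[1], 0)

  # concatenating epochs reproduces the kept prefix exactly
  flat <- do.call(cbind, lapply(seq_len(dim(ep)[1]), function(e) ep[e, , ]))
  expect_equal(unname(flat), unname(rec$data[, seq_len(60 * 200)]))
})

test_that("differential entropy follows the Gaussian closed form", {
  set.seed(1)
  x <- rnorm(2e5)
  expect_equal(differential_entropy(x), 0.5 * log(2 * pi * exp(1)),
               tolerance = 0.02)

  # scale property: doubling amplitude adds exactly ln 2
  y <- rnorm(500)
  expect_equal(differential_entropy(2 * y),
               differential_entropy(y) + log(2), tolerance = 1e-12)

  # hand-computed variance for [1, -1, 1, -1]
  expect_equal(differential_entropy(c(1, -1, 1, -1)),
               0.5 * log(2 * pi * exp(1) * 4 / 3), tolerance = 1e-12)

  expect_warning(de0 <- differential_entropy(rep(1, 10)), "zero-variance")
  expect_identical(de0, -Inf)

  # monotone in variance
  des <- vapply(c(0.5, 1, 2, 4), function(s) {
    set.seed(7); differential_entropy(rnorm(1000, sd = s))
  }, numeric(1))
  expect_true(all(diff(des) > 0))
})

test_that("DE feature extraction has the contracted geometry", {
  rec <- preprocess_eeg(tiny_eeg(4, 5, seed = 2))
  fs <- extract_de_features(rec)
  expect_equal(ncol(fs$features), 4 * 5)
  expect_equal(nrow(fs$features), 5)
  expect_equal(colnames(fs$features)[1:5],
               paste("FP1", c("delta", "theta", "alpha", "beta", "gamma"),
                     sep = "."))

  # full montage width: 60 channels x 5 bands = 300
  rec60 <- preprocess_eeg(tiny_eeg(60, 2, seed = 3))
  expect_equal(ncol(extract_de_features(rec60)$features), 300)

  # doubling the signal shifts every DE by ln 2
  rec2 <- rec
  rec2$data <- rec2$data * 2
  fs2 <- extract_de_features(rec2)
  expect_equal(fs2$features, fs$features + log(2), tolerance = 1e-9)
})

test_that("narrowband signals concentrate DE in their band", {
  fs <- 200
  t <- seq(0, 5 - 1 / fs, by = 1 / fs)
  sig <- matrix(rep(sin(2 * pi * 10 * t), 3), 3, byrow = TRUE) +
    matrix(rnorm(3 * length(t), 0, 0.01), 3)
  rec <- eeg_recording(sig, fs)
  f <- extract_de_features(rec)
  alpha <- f$features[, grepl("alpha", colnames(f$features))]
  gamma <- f$features[, grepl("gamma", colnames(f$features))]
  expect_true(all(alpha > gamma))
})

test_that("feature extraction is channel-permutation equivariant", {
  rec <- preprocess_eeg(tiny_eeg(4, 3, seed = 9))
  f <- extract_de_features(rec)
  perm <- c(3, 1, 4, 2)
  rec_p <- eeg_recording(rec$data[perm, ], rec$fs,
                         rec$channel_names[perm], rec$meta)
  f_p <- extract_de_features(rec_p)
  reorder <- as.vector(t(outer((perm - 1) * 5, 1:5, "+")))
  expect_equal(unname(f_p$features), unname(f$features[, reorder]),
               tolerance = 1e-12)
})

test_that("per-emotion mean DE tracks the configured band-power ordering", {
  p <- eeg_gen_params(n_channels = 2, epoch_jitter_sd = 0.1, noise_sd = 0.2)
  prof <- p$band_power_profile
  mean_de <- sapply(c("calmness", "fear"), function(em) {
    des <- lapply(1:15, function(s) {
      rec <- preprocess_eeg(generate_eeg_trial(em, 2, p, seed = 100 + s))
      colMeans(extract_de_features(rec)$features)
    })
    colMeans(do.call(rbind, des))
  })
  for (b in c("alpha", "gamma")) {
    cols <- grepl(b, rownames(mean_de))
    want <- sign(prof["calmness", b] - prof["fear", b])
    expect_true(all(sign(mean_de[cols, "calmness"] -
                           mean_de[cols, "fear"]) == want))
  }
})
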