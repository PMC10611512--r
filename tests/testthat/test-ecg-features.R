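test_that("ECG preprocessing removes DC and out-of-band interference", {
  fs <- 1000
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  mk <- function(x) structure(list(data = x, fs = fs, meta = list()),
                              class = "emorec_ecg")
  # DC: removed up to the zero-phase filter's edge transients (both ends),
  # so judge the steady state over the middle of the record
  dc <- preprocess_ecg(mk(rep(1, length(t))))
  expect_lt(abs(mean(dc$data[801:1200])), 0.01)

  hum <- preprocess_ecg(mk(sin(2 * pi * 50 * t)))
  expect_lt(sqrt(mean(hum$data^2)), 0.1 * sqrt(0.5))

  expect_equal(length(preprocess_ecg(mk(rnorm(10000)))$data), 2000)
  expect_equal(dc$fs, 200)
})

test_that("R-peak detection is sensitive, refractory and equivariant", {
  tr <- generate_ecg_trial("calmness", 80, seed = 5)
  rr <- detect_r_peaks(preprocess_ecg(tr))
  hit <- vapply(tr$peak_times,
                function(g) any(abs(rr$peak_times - g) <= 0.03), logical(1))
  expect_gte(mean(hit), 0.99)
  expect_true(all(diff(rr$peak_times) >= 0.25))

  flat <- structure(list(data = rep(0, 2000), fs = 200, meta = list()),
                    class = "emorec_ecg")
  expect_error(detect_r_peaks(flat))

  # time-shift equivariance: prepend half a second of baseline
  pp <- preprocess_ecg(tr)
  shifted <- pp
  shifted$data <- c(rep(0, 100), pp$data)
  rr_s <- detect_r_peaks(shifted)
  n <- min(length(rr$peak_times), length(rr_s$peak_times))
  expect_equal(rr_s$peak_times[seq_len(n)] - 0.5,
               rr$peak_times[seq_len(n)], tolerance = 0.02)
})

test_that("time-domain features follow the printed estimators", {
  rr <- rr_series(cumsum(c(0, rep(0.8, 4))))
  td <- hrv_time_domain(rr)
  expect_equal(td$sdnn, 0)
  expect_equal(td$rmssd, 0)
  expect_equal(td$nn50, 0)

  rr2 <- rr_series(cumsum(c(0, 0.80, 0.86, 0.78)))
  td2 <- hrv_time_domain(rr2)
  expect_equal(td2$nn50, 2)
  expect_equal(td2$rmssd, sqrt((0.06^2 + 0.08^2) / 2), tolerance = 1e-12)
  expect_equal(td2$pnn50, 100)

  rr3 <- rr_series(cumsum(c(0, 0.7, 0.9)))
  expect_equal(hrv_time_domain(rr3)$sdnn, 0.1, tolerance = 1e-12)

  expect_error(hrv_time_domain(rr_series(c(0, 1))), "at least 2")
})

test_that("time/geometric/DFA/ApEn agree with naive oracles", {
  set.seed(14)
  for (r in 1:10) {
    rr <- 0.8 + 0.05 * rnorm(sample(50:200, 1))
    obj <- rr_series(cumsum(c(0, rr)), clean = FALSE)
    td <- hrv_time_domain(obj)
    expect_equal(td$sdnn, oracle_sdnn(rr), tolerance = 1e-10)
    expect_equal(td$rmssd, oracle_rmssd(rr), tolerance = 1e-10)
    expect_equal(td$sdsd, oracle_sdsd(rr), tolerance = 1e-10)
  }
  x <- 0.8 + 0.05 * rnorm(200)
  d <- dfa(x)
  for (s in c(4, 8, 16, 40, 64)) {
    expect_equal(d$fluctuation[d$scales == s], oracle_dfa_f(x, s),
                 tolerance = 1e-10)
  }
  y <- rnorm(80)
  expect_equal(apen(y, 2, 0.25), oracle_apen(y, 2, 0.25), tolerance = 1e-10)
})

test_that("geometric features reflect the RR histogram", {
  # single-bin histogram
  geo0 <- hrv_geometric(rr_series(cumsum(c(0, rep(0.8, 30)))))
  expect_equal(geo0$tri, 1)
  expect_lte(geo0$tinn, 3 * 1000 / 128)

  # uniform over k bins with equal counts -> TRI = k
  bw <- 1 / 128
  rr_u <- rep(0.7 + bw * (0:4) + bw / 2, each = 8)
  geo_u <- hrv_geometric(rr_series(cumsum(c(0, rr_u)), clean = FALSE))
  expect_equal(geo_u$tri, 5)

  # triangular distribution: TINN approximates the base width
  set.seed(4)
  tri_rr <- 0.8 + (runif(400, -1, 1) + runif(400, -1, 1)) * 0.1 / 2
  geo_t <- hrv_geometric(rr_series(cumsum(c(0, tri_rr)), clean = FALSE))
  expect_lt(abs(geo_t$tinn - 200), 40)

  expect_warning(hrv_geometric(rr_series(cumsum(c(0, rep(0.8, 5))))),
                 "too few")
})

test_that("spectral features localize modulation in the right band", {
  # build a tachogram directly: constant RR plus one sinusoidal modulation
  build <- function(f, dur = 400) {
    t_cur <- 0
    peaks <- 0
    while (t_cur < dur) {
      d <- 0.9 + 0.05 * sin(2 * pi * f * t_cur)
      t_cur <- t_cur + d
      peaks <- c(peaks, t_cur)
    }
    rr_series(peaks, clean = FALSE)
  }
  hf_only <- hrv_frequency_domain(build(0.25))
  expect_gt(hf_only$hf, 5 * hf_only$lf)
  expect_lt(hf_only$lf_hf, 0.2)

  lf_only <- hrv_frequency_domain(build(0.1))
  expect_gt(lf_only$lf_hf, 5)

  const <- hrv_frequency_domain(rr_series(seq(0, 300, by = 0.8)))
  expect_lt(const$lf + const$hf + const$vlf, 1e-8)

  short <- rr_series(seq(0, 30, by = 0.8))
  expect_warning(fq <- hrv_frequency_domain(short), "too short")
  expect_true(is.na(fq$lf))
})

test_that("DFA exponents match theory for white and integrated noise", {
  set.seed(21)
  a1 <- replicate(25, dfa(rnorm(1000))$alpha1)
  expect_gt(mean(a1), 0.4)
  expect_lt(mean(a1), 0.65)
  ab <- replicate(25, dfa(cumsum(rnorm(1000)))$alpha1)
  expect_gt(mean(ab), 1.35)
  expect_lt(mean(ab), 1.65)
})

test_that("approximate entropy ranks regularity", {
  expect_equal(apen(rep(1, 50), 2, 0.2), 0)
  alt <- rep(c(1, -1), 30)
  expect_equal(apen(alt, 2, 0.5), oracle_apen(alt, 2, 0.5), tolerance = 1e-12)
  expect_lt(apen(alt, 2, 0.5), 1e-3)
  expect_error(apen(rnorm(50), 2, 0), "positive")

  set.seed(8)
  wins <- 0
  for (r in 1:10) {
    x <- rnorm(150)
    if (apen(x, 2, 0.2 * sd(x)) > apen(sort(x), 2, 0.2 * sd(x))) {
      wins <- wins + 1
    }
  }
  expect_equal(wins, 10)
})

test_that("the assembled HRV vector is 19-dimensional and scales correctly", {
  tr <- generate_ecg_trial("happiness", 120, seed = 3)
  rr <- rr_series(tr$peak_times)
  v <- extract_hrv_vector(rr)
  expect_length(v, 19)
  expect_equal(names(v)[c(1, 8, 14, 19)], c("SDNN", "VLF", "alpha1", "HR"))

  rr_const <- rr_series(seq(0, 100, by = 1))
  expect_equal(unname(extract_hrv_vector(rr_const)["HR"]), 60)

  # doubling all intervals halves HR, scales time-domain features by 2,
  # and leaves ApEn invariant when r scales along
  v1 <- extract_hrv_vector(rr)
  rr2 <- rr_series(rr$peak_times * 2)
  v2 <- extract_hrv_vector(rr2)
  expect_equal(unname(v2["HR"]), unname(v1["HR"]) / 2, tolerance = 1e-9)
  for (f in c("SDNN", "RMSSD", "SDSD", "SD1", "SD2")) {
    expect_equal(unname(v2[f]), 2 * unname(v1[f]), tolerance = 1e-6)
  }
  expect_equal(unname(v2["ApEn"]), unname(v1["ApEn"]), tolerance = 1e-9)
  expect_equal(unname(v2["alpha1"]), unname(v1["alpha1"]), tolerance = 1e-9)
})

test_that("window segmentation implements the 60 s / 55 s overlap grid", {
  mk <- function(dur) structure(list(data = rep(0, dur * 200), fs = 200),
                                class = "emorec_ecg")
  expect_length(segment_windows(mk(80)), 5)
  expect_length(segment_windows(mk(60)), 1)
  expect_warning(w <- segment_windows(mk(59)), "shorter")
  expect_length(w, 0)
  s <- segment_windows(mk(70))
  expect_equal(vapply(s, `[[`, numeric(1), "start"), c(0, 5, 10))
})
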