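# Independent naive oracles (deliberately loop-based, no vectorization
# tricks) used to cross-check the package implementations.

oracle_sdnn <- function(rr) {
  n <- length(rr)
  m <- 0
  for (i in seq_len(n)) m <- m + rr[i]
  m <- m / n
  s <- 0
  for (i in seq_len(n)) s <- s + (rr[i] - m)^2
  sqrt(s / n)
}

oracle_rmssd <- function(rr) {
  n <- length(rr)
  s <- 0
  for (i in seq_len(n - 1)) s <- s + (rr[i + 1] - rr[i])^2
  sqrt(s / (n - 1))
}

oracle_sdsd <- function(rr) {
  n <- length(rr)
  d <- numeric(n - 1)
  for (i in seq_len(n - 1)) d[i] <- rr[i + 1] - rr[i]
  md <- 0
  for (i in seq_along(d)) md <- md + d[i]
  md <- md / length(d)
  s <- 0
  for (i in seq_along(d)) s <- s + (d[i] - md)^2
  sqrt(s / length(d))
}

# DFA fluctuation at one scale: integrate, box, per-box least-squares
# line, RMS of residuals (trailing remainder dropped).
oracle_dfa_f <- function(x, s) {
  n <- length(x)
  xb <- mean(x)
  y <- numeric(n)
  acc <- 0
  for (i in seq_len(n)) {
    acc <- acc + x[i] - xb
    y[i] <- acc
  }
  nseg <- floor(n / s)
  tot <- 0
  cnt <- 0
  for (seg in seq_len(nseg)) {
    idx <- ((seg - 1) * s + 1):(seg * s)
    tt <- seq_len(s)
    fit <- stats::lm(y[idx] ~ tt)
    res <- y[idx] - stats::fitted(fit)
    for (k in seq_len(s)) {
      tot <- tot + res[k]^2
      cnt <- cnt + 1
    }
  }
  as.numeric(sqrt(tot / cnt))
}

# Approximate entropy straight from the template-matching definition
# (self-matches included, strict < r, Chebyshev distance).
oracle_apen <- function(x, m, r) {
  n <- length(x)
  phi <- function(mm) {
    nt <- n - mm + 1
    logs <- numeric(nt)
    for (i in seq_len(nt)) {
      cnt <- 0
      for (j in seq_len(nt)) {
        dmax <- 0
        for (k in 0:(mm - 1)) {
          dd <- abs(x[i + k] - x[j + k])
          if (dd > dmax) dmax <- dd
        }
        if (dmax < r) cnt <- cnt + 1
      }
      logs[i] <- log(cnt / nt)
    }
    mean(logs)
  }
  phi(m) - phi(m + 1)
}

# Krippendorff's alpha from first principles: observed disagreement from
# ordered pairs within units, expected from all pooled pairs.
oracle_kripp_interval <- function(scores) {
  vals <- as.vector(scores)
  n_units <- ncol(scores)
  num <- 0
  den_pairs <- 0
  for (u in seq_len(n_units)) {
    xs <- scores[, u]
    m <- length(xs)
    if (m < 2) next
    for (i in seq_len(m)) for (j in seq_len(m)) {
      if (i != j) num <- num + (xs[i] - xs[j])^2 / (m - 1)
    }
    den_pairs <- den_pairs + m
  }
  d_o <- num / den_pairs
  tot <- 0
  np <- 0
  for (i in seq_along(vals)) for (j in seq_along(vals)) {
    if (i != j) {
      tot <- tot + (vals[i] - vals[j])^2
      np <- np + 1
    }
  }
  d_e <- tot / np
  1 - d_o / d_e
}

# Short deterministic EEG recording for feature tests.
tiny_eeg <- function(n_channels = 4, duration = 4, fs = 1000, seed = 1,
                     emotion = "happiness", ...) {
  p <- eeg_gen_params(n_channels = n_channels, fs_raw = fs, ...)
  generate_eeg_trial(emotion, duration, p, seed = seed)
}
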