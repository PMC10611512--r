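# Internal helpers: seeded RNG scoping, zero-phase filtering, Welch PSD.

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards. `seed = NULL` leaves the
# global stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647L))
  expr
}

# Deterministic sub-stream seeds, kept below 2^31.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed %% 2147483647)
  primes <- c(7919, 104729, 1299709, 15485863, 32452843)
  for (k in seq_along(idx)) {
    s <- (s * 69069 + idx[k] * primes[((k - 1L) %% 5L) + 1L] + 1) %% 2147483647
  }
  as.integer(s)
}

# Zero-phase Butterworth band-pass applied column-wise to a matrix, with
# reflective padding to tame startup transients (same idea as
# signal::filtfilt, vectorized over columns via stats::filter).
design_butter <- function(order, lo, hi, fs, type = "pass") {
  nyq <- fs / 2
  w <- if (type == "pass" || type == "stop") c(lo, hi) / nyq else lo / nyq
  flt <- signal::butter(order, w, type = type)
  list(b = as.numeric(flt$b), a = as.numeric(flt$a))
}

# Forward-backward (zero-phase) filtering of every column of `x`
# (compiled hot path; reflective end padding like signal::filtfilt).
filtfilt_mat <- function(flt, x) {
  x <- as.matrix(x)
  npad <- 3L * (max(length(flt$a), length(flt$b)) - 1L)
  iir_filtfilt_mat(flt$b, flt$a, x, npad)
}

filtfilt_vec <- function(flt, x) {
  as.numeric(filtfilt_mat(flt, matrix(x, ncol = 1L)))
}

# Welch power spectral density (one-sided, density scaling), Hann window,
# 50% overlap. Returns data.frame(freq, psd).
welch_psd <- function(x, fs, nperseg = min(length(x), 256L)) {
  n <- length(x)
  nperseg <- min(nperseg, n)
  step <- max(1L, floor(nperseg / 2))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nperseg) / (nperseg + 1))
  u <- sum(w^2)
  acc <- 0
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    seg <- (seg - mean(seg)) * w
    acc <- acc + Mod(stats::fft(seg))^2
  }
  pxx <- acc / length(starts) / (fs * u)
  half <- seq_len(floor(nperseg / 2) + 1L)
  pxx <- pxx[half]
  # double everything except DC (and Nyquist when nperseg even)
  dbl <- rep(2, length(half))
  dbl[1L] <- 1
  if (nperseg %% 2L == 0L) dbl[length(half)] <- 1
  data.frame(freq = (half - 1L) * fs / nperseg, psd = pxx * dbl)
}

trapz <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
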