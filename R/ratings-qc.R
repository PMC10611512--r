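#' Dichotomize Likert scores into a high/low bit vector
#'
#' Scores strictly above the threshold are "high" (bit 1); scores at or
#' below it are "low" (bit 0). Ties at the threshold deliberately go to the
#' low set (one convention, applied everywhere).
#'
#' @param scores integer scores in 1..5 (one annotator's clip ratings).
#' @param threshold dichotomization threshold (default 3).
#' @return integer 0/1 vector of the same length.
#' @examples
#' dichotomize(c(5, 4, 3, 2, 1))
#' @export
dichotomize <- function(scores, threshold = 3) {
  if (any(scores < 1 | scores > 5)) stop("scores must lie in 1..5")
  as.integer(scores > threshold)
}

#' Normalized disagreement distance between two high/low vectors
#'
#' Distance between two annotators' dichotomized rating vectors:
#' one minus the fraction of positions at which the bits agree. (Despite
#' the "Jaccard" name common in the stimulus-curation literature, the
#' quantity is a normalized Hamming disagreement: agreement counts matching
#' zeros as well as matching ones.) Symmetric, zero for identical vectors,
#' one for complementary vectors.
#'
#' @param h_i,h_j equal-length 0/1 vectors.
#' @return distance in \[0, 1\].
#' @examples
#' jaccard_distance(c(1, 1, 0, 0), c(1, 0, 0, 1)) # 0.5
#' @export
jaccard_distance <- function(h_i, h_j) {
  if (length(h_i) != length(h_j)) stop("length mismatch")
  1 - sum(h_i == h_j) / length(h_i)
}

rating_distance_matrix <- function(scores, threshold = 3) {
  H <- t(apply(scores, 1L, dichotomize, threshold = threshold))
  n <- ncol(H)
  D <- 1 - (tcrossprod(H) + tcrossprod(1L - H)) / n
  dimnames(D) <- list(rownames(scores), rownames(scores))
  D
}

#' Annotator outlier detection from pairwise rating distances
#'
#' Builds the annotators x annotators disagreement matrix D from
#' dichotomized ratings on one scale, takes the standard deviation of D's
#' strict upper-triangular entries as the reference dispersion, and flags
#' annotators whose distance profile deviates from the panel by more than
#' `factor` times that dispersion.
#'
#' Row statistic. The default (`row_stat = "mean"` with `center = TRUE`)
#' flags annotator i when the mean off-diagonal distance of row i exceeds
#' the median of those row means by more than `factor` times the reference
#' dispersion -- the classical MAD-style deviation rule. A literal variant
#' that compares the per-row standard deviation directly against
#' `factor` times the dispersion is available (`row_stat = "sd"`,
#' `center = FALSE`); note that a uniformly random annotator has a
#' *homogeneous* distance profile, so the row-SD statistic cannot detect
#' gross random disagreement (see the methods vignette).
#'
#' @param table an `emorec_ratings` object (or a bare score matrix).
#' @param scale which scale to analyze (`"valence"` or `"arousal"`).
#' @param factor multiplier on the reference dispersion (default 1.5).
#' @param threshold dichotomization threshold.
#' @param row_stat `"mean"` (default) or `"sd"` summary of each
#'   annotator's off-diagonal distances.
#' @param center subtract the median row statistic before comparing
#'   (default TRUE).
#' @param dispersion `"sd"` (default) of the triangular entries, or
#'   `"mad"` for the median absolute deviation variant (sensitivity
#'   analysis).
#' @return object of class `emorec_outliers`: list with `distance_matrix`,
#'   `row_stat`, `mad_value` (the reference dispersion), `removed`
#'   (integer annotator indices), `factor`, and `degenerate` flag.
#' @examples
#' rt <- generate_ratings(10, 29, outlier_ids = 3, seed = 1)
#' detect_outliers(rt, "valence")$removed
#' @export
detect_outliers <- function(table, scale = c("valence", "arousal"),
                            factor = 1.5, threshold = 3,
                            row_stat = c("mean", "sd"), center = TRUE,
                            dispersion = c("sd", "mad")) {
  row_stat <- match.arg(row_stat)
  dispersion <- match.arg(dispersion)
  scores <- if (inherits(table, "emorec_ratings")) {
    scale <- match.arg(scale)
    table[[scale]]
  } else {
    as.matrix(table)
  }
  if (nrow(scores) < 3L) stop("need at least 3 annotators")
  D <- rating_distance_matrix(scores, threshold)
  tri <- D[upper.tri(D)]
  ref <- if (dispersion == "sd") stats::sd(tri) else stats::mad(tri)
  degenerate <- !is.finite(ref) || ref <= .Machine$double.eps
  n <- nrow(D)
  rs <- vapply(seq_len(n), function(i) {
    v <- D[i, -i]
    if (row_stat == "mean") mean(v) else stats::sd(v)
  }, numeric(1))
  stat <- if (center) rs - stats::median(rs) else rs
  removed <- if (degenerate) integer() else which(stat > factor * ref)
  if (degenerate) {
    warning("degenerate distance matrix (zero dispersion); no outliers flagged")
  }
  structure(
    list(distance_matrix = D, row_stat = rs, deviation = stat,
         mad_value = ref, removed = as.integer(removed), factor = factor,
         degenerate = degenerate),
    class = "emorec_outliers"
  )
}

#' @export
print.emorec_outliers <- function(x, ...) {
  cat(sprintf(
    "Annotator outlier report: %d annotators, dispersion %.4f, factor %.2f\n",
    nrow(x$distance_matrix), x$mad_value, x$factor
  ))
  if (length(x$removed)) {
    cat("  removed:", paste(x$removed, collapse = ", "), "\n")
  } else {
    cat("  removed: none\n")
  }
  invisible(x)
}

#' Krippendorff's alpha inter-rater reliability
#'
#' Coincidence-matrix Krippendorff's alpha for a raters x units score
#' matrix, with the interval difference metric by default (five-point
#' Likert scales treated numerically) or the ordinal metric.
#'
#' @param table an `emorec_ratings` object or a raters x units matrix.
#' @param scale scale name when `table` is an `emorec_ratings`.
#' @param metric `"interval"` (default) or `"ordinal"`.
#' @return alpha in (-1, 1\]; defined as 1 when expected disagreement is 0.
#' @examples
#' m <- rbind(c(1, 2, 3, 4), c(1, 2, 3, 4))
#' krippendorff_alpha(m) # 1
#' @export
krippendorff_alpha <- function(table, scale = "valence",
                               metric = c("interval", "ordinal")) {
  metric <- match.arg(metric)
  scores <- if (inherits(table, "emorec_ratings")) table[[scale]]
            else as.matrix(table)
  if (nrow(scores) < 2L) stop("need at least 2 annotators")
  vals <- sort(unique(as.vector(scores)))
  v <- length(vals)
  idx <- matrix(match(scores, vals), nrow(scores), ncol(scores))
  # coincidence matrix: for each unit with m>=2 ratings add
  # n_uc * n_uk / (m - 1) for c != k, n_uc*(n_uc-1)/(m-1) on the diagonal
  co <- matrix(0, v, v)
  for (u in seq_len(ncol(idx))) {
    cnt <- tabulate(idx[, u], nbins = v)
    m <- sum(cnt)
    if (m < 2L) next
    pair <- outer(cnt, cnt)
    diag(pair) <- cnt * (cnt - 1)
    co <- co + pair / (m - 1)
  }
  nc <- rowSums(co)
  ntot <- sum(nc)
  if (metric == "interval") {
    delta <- outer(vals, vals, function(a, b) (a - b)^2)
  } else {
    # ordinal: squared sum of marginal frequencies between the two ranks
    cum <- cumsum(nc)
    delta <- matrix(0, v, v)
    for (i in seq_len(v)) for (j in seq_len(v)) {
      if (i != j) {
        lo <- min(i, j); hi <- max(i, j)
        delta[i, j] <- (sum(nc[lo:hi]) - (nc[lo] + nc[hi]) / 2)^2
      }
    }
  }
  d_o <- sum(co * delta)
  d_e <- (outer(nc, nc) * delta) |> sum()
  d_e <- d_e / (ntot - 1)
  if (d_e <= .Machine$double.eps) return(1)
  1 - d_o / d_e
}

#' Cohen's kappa between two categorical labelings
#'
#' Chance-corrected agreement (p_o - p_e) / (1 - p_e) between two raters'
#' label vectors. Defined as 1 when chance agreement is 1 and the
#' labelings are identical, 0 otherwise.
#'
#' @param labels_a,labels_b equal-length label vectors.
#' @return kappa in \[-1, 1\].
#' @examples
#' cohen_kappa(c(1, 1, 2, 2), c(1, 2, 2, 2))
#' @export
cohen_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) stop("length mismatch")
  lev <- union(unique(labels_a), unique(labels_b))
  a <- factor(labels_a, levels = lev)
  b <- factor(labels_b, levels = lev)
  tab <- table(a, b) / length(a)
  p_o <- sum(diag(tab))
  p_e <- sum(rowSums(tab) * colSums(tab))
  if (1 - p_e <= .Machine$double.eps) {
    return(if (p_o >= 1 - .Machine$double.eps) 1 else 0)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Valence-arousal regression over clip mean ratings
#'
#' Ordinary least squares of clip-mean arousal on clip-mean valence,
#' restricted to clips on one side of the valence midpoint (clip-mean
#' valence > 3 for `"high"`, < 3 for `"low"`). Clip means are used (the
#' mean location of each stimulus on the affect plane).
#'
#' @param table an `emorec_ratings` object.
#' @param valence_side `"high"` or `"low"`.
#' @return object of class `emorec_regression`: list with `r_squared`,
#'   `f_value`, `p_value`, `slope`, `intercept`, `ci95_band` (data.frame
#'   of fit and 95% confidence band over the observed valence range),
#'   `n_clips`, and the underlying `lm` fit.
#' @export
va_regression <- function(table, valence_side = c("high", "low")) {
  valence_side <- match.arg(valence_side)
  vm <- colMeans(table$valence)
  am <- colMeans(table$arousal)
  keep <- if (valence_side == "high") vm > 3 else vm < 3
  if (sum(keep) < 3L) stop("need at least 3 clips on the requested side")
  d <- data.frame(valence = vm[keep], arousal = am[keep])
  fit <- stats::lm(arousal ~ valence, data = d)
  sm <- summary(fit)
  grid <- data.frame(valence = seq(min(d$valence), max(d$valence),
                                   length.out = 50))
  ci <- stats::predict(fit, grid, interval = "confidence", level = 0.95)
  structure(
    list(
      r_squared = sm$r.squared,
      f_value = unname(sm$fstatistic[1]),
      p_value = unname(stats::pf(sm$fstatistic[1], sm$fstatistic[2],
                                 sm$fstatistic[3], lower.tail = FALSE)),
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      ci95_band = cbind(grid, as.data.frame(ci)),
      n_clips = nrow(d),
      fit = fit
    ),
    class = "emorec_regression"
  )
}

#' @export
print.emorec_regression <- function(x, ...) {
  cat(sprintf(
    "Arousal ~ valence (n = %d clips): R^2 = %.4f, F = %.4f, p = %.3g, b = %.4f\n",
    x$n_clips, x$r_squared, x$f_value, x$p_value, x$slope
  ))
  invisible(x)
}
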