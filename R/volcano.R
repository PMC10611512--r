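#' Per-subject positive/negative group means along an affect dimension
#'
#' Maps each sample's emotion to its consensus score on the chosen
#' dimension, then averages each subject's feature vectors over samples
#' scoring above the threshold (positive group) and below it (negative
#' group); samples exactly at the threshold are excluded. Subjects with
#' an empty group are dropped with a warning.
#'
#' @param dataset an `emorec_dataset` (per-epoch EEG features).
#' @param scores named per-emotion consensus scores; defaults to
#'   [consensus_scores()] for the dimension.
#' @param dimension `"valence"` or `"arousal"`.
#' @param threshold split point on the 1-5 scale (default 3).
#' @return object of class `emorec_groups`: list with `positive`,
#'   `negative` (subjects x features matrices), `dimension`, `subjects`,
#'   `feature_names`.
#' @export
group_by_dimension <- function(dataset, scores = NULL,
                               dimension = c("valence", "arousal"),
                               threshold = 3) {
  dimension <- match.arg(dimension)
  scores <- scores %||% consensus_scores(dimension)
  labs <- dataset$labels
  missing <- setdiff(unique(labs$emotion), names(scores))
  if (length(missing)) {
    stop("no consensus score for emotion(s): ",
         paste(missing, collapse = ", "))
  }
  sc <- scores[labs$emotion]
  subjects <- sort(unique(labs$subject))
  pos <- list(); neg <- list(); kept <- c()
  for (s in subjects) {
    rows_p <- labs$subject == s & sc > threshold
    rows_n <- labs$subject == s & sc < threshold
    if (!any(rows_p) || !any(rows_n)) {
      warning("subject ", s, " has an empty group; excluded")
      next
    }
    pos[[length(pos) + 1L]] <-
      colMeans(dataset$features[rows_p, , drop = FALSE])
    neg[[length(neg) + 1L]] <-
      colMeans(dataset$features[rows_n, , drop = FALSE])
    kept <- c(kept, s)
  }
  if (!length(kept)) stop("all subjects have an empty group")
  structure(
    list(positive = do.call(rbind, pos), negative = do.call(rbind, neg),
         dimension = dimension, subjects = kept,
         feature_names = colnames(dataset$features)),
    class = "emorec_groups"
  )
}

#' Volcano-plot differential statistics
#'
#' Per feature: the fold change F is the ratio of the across-subject mean
#' of the positive-group means to that of the negative-group means; the
#' p-value comes from a paired t-test (default) or a Kruskal-Wallis test
#' across subjects. A feature is called up-regulated when F > 201/200
#' with p below `alpha`, down-regulated when F < 200/201 with p below
#' `alpha`, otherwise none. No multiple-testing correction is applied by
#' default (the volcano thresholds are raw alpha lines); Benjamini-
#' Hochberg adjustment is available via `adjust`. Features with a
#' non-positive group mean get an undefined fold change (NA, regulation
#' "none"); their p-value is still computed.
#'
#' @param groups an `emorec_groups` with at least 3 subjects.
#' @param alpha significance level (default 0.05).
#' @param test `"paired_t"` (default) or `"kruskal"`.
#' @param f_up,f_down regulation thresholds on F.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame of class `emorec_volcano`: columns `feature`,
#'   `channel`, `band`, `f`, `log2_f`, `p`, `neg_log10_p`, `regulation`,
#'   `significant`, plus attributes `dimension`, `alpha`, `test`.
#' @export
volcano_stats <- function(groups, alpha = 0.05,
                          test = c("paired_t", "kruskal"),
                          f_up = 201 / 200, f_down = 200 / 201,
                          adjust = c("none", "BH")) {
  test <- match.arg(test)
  adjust <- match.arg(adjust)
  P <- groups$positive
  N <- groups$negative
  ns <- nrow(P)
  if (ns < 3L) stop("need at least 3 subjects with both groups")
  mp <- colMeans(P)
  mn <- colMeans(N)
  f <- ifelse(mp > 0 & mn > 0, mp / mn, NA_real_)
  if (test == "paired_t") {
    d <- P - N
    dbar <- colMeans(d)
    dsd <- apply(d, 2L, stats::sd)
    tstat <- dbar / (dsd / sqrt(ns))
    p <- 2 * stats::pt(-abs(tstat), df = ns - 1)
    p[dsd == 0] <- ifelse(dbar[dsd == 0] == 0, 1, 0)
  } else {
    p <- vapply(seq_len(ncol(P)), function(j) {
      stats::kruskal.test(list(P[, j], N[, j]))$p.value
    }, numeric(1))
  }
  p_eff <- if (adjust == "BH") stats::p.adjust(p, "BH") else p
  sig <- p_eff < alpha
  reg <- rep("none", length(f))
  reg[sig & !is.na(f) & f > f_up] <- "up"
  reg[sig & !is.na(f) & f < f_down] <- "down"
  nm <- groups$feature_names %||% paste0("f", seq_along(f))
  parts <- strsplit(nm, ".", fixed = TRUE)
  out <- data.frame(
    feature = nm,
    channel = vapply(parts, function(z) z[1], character(1)),
    band = vapply(parts, function(z) if (length(z) > 1L) z[2] else NA_character_,
                  character(1)),
    f = f, log2_f = log2(f), p = p, neg_log10_p = -log10(p),
    regulation = reg, significant = sig,
    stringsAsFactors = FALSE
  )
  attr(out, "dimension") <- groups$dimension
  attr(out, "alpha") <- alpha
  attr(out, "test") <- test
  class(out) <- c("emorec_volcano", "data.frame")
  out
}

#' Map regulation calls onto the scalp layout
#'
#' Joins each volcano point's channel to its 2-D layout coordinates,
#' producing a per-band, per-channel regulation table (up = red,
#' down = blue by convention). Non-significant features carry "none".
#'
#' @param points an `emorec_volcano` table.
#' @param layout data.frame(channel, x, y), e.g. [channel_layout()].
#' @return data.frame of class `emorec_topography`: `band`, `channel`,
#'   `x`, `y`, `regulation`.
#' @export
map_topography <- function(points, layout = channel_layout()) {
  idx <- match(points$channel, layout$channel)
  if (anyNA(idx)) {
    stop("unknown channel(s): ",
         paste(unique(points$channel[is.na(idx)]), collapse = ", "))
  }
  out <- data.frame(
    band = points$band, channel = points$channel,
    x = layout$x[idx], y = layout$y[idx],
    regulation = points$regulation, stringsAsFactors = FALSE
  )
  class(out) <- c("emorec_topography", "data.frame")
  out
}

#' Cross-session shrinkage of differential features
#'
#' For each band (and the grouping dimension), counts the significant
#' features and the mean |log2 F| per session. A band receives a
#' "shrinkage" verdict when both quantities are non-increasing across
#' sessions and at least one strictly decreases overall -- the signature
#' of volcano points collapsing toward the origin as negative emotion
#' categories accumulate.
#'
#' @param session_points list of `emorec_volcano` tables, one per
#'   session, in session order, with identical feature ordering.
#' @return data.frame of class `emorec_shrinkage`: one row per band with
#'   per-session significant counts `n_sig_s<k>`, mean absolute log2
#'   fold-changes `mlfc_s<k>`, and logical `shrinkage`.
#' @export
cross_session_shrinkage <- function(session_points) {
  stopifnot(length(session_points) >= 2L)
  feats <- lapply(session_points, function(p) p$feature)
  if (!all(vapply(feats[-1], identical, logical(1), feats[[1]]))) {
    stop("feature ordering differs across sessions")
  }
  bands <- unique(session_points[[1]]$band)
  ns <- length(session_points)
  rows <- lapply(bands, function(b) {
    n_sig <- vapply(session_points, function(p) {
      sum(p$significant[p$band == b], na.rm = TRUE)
    }, numeric(1))
    mlfc <- vapply(session_points, function(p) {
      v <- abs(p$log2_f[p$band == b])
      mean(v[is.finite(v)])
    }, numeric(1))
    verdict <- all(diff(n_sig) <= 0) && all(diff(mlfc) <= 1e-12) &&
      (n_sig[1] > n_sig[ns] || mlfc[1] > mlfc[ns])
    d <- data.frame(band = b, shrinkage = verdict)
    for (k in seq_len(ns)) {
      d[[sprintf("n_sig_s%d", k)]] <- n_sig[k]
      d[[sprintf("mlfc_s%d", k)]] <- mlfc[k]
    }
    d
  })
  out <- do.call(rbind, rows)
  class(out) <- c("emorec_shrinkage", "data.frame")
  out
}
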