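#' Generate a synthetic annotator rating table
#'
#' Emulates a panel of annotators scoring video clips on five-point Likert
#' scales (valence, arousal, dominance, liking, familiarity). Consistent
#' annotators draw each clip's score from a clip-specific latent mean plus
#' Gaussian rater noise, rounded and clipped to 1..5; annotators listed in
#' `outlier_ids` ignore the latent structure and answer uniformly at
#' random, which is the planted pathology the outlier-rejection rule is
#' expected to catch.
#'
#' @param n_annotators number of annotators (rows), at least 3.
#' @param n_clips number of clips (columns), at least 2.
#' @param outlier_ids integer vector of annotator indices that respond
#'   uniformly at random (may be empty).
#' @param noise_sd Gaussian rater noise SD on the 1-5 scale for consistent
#'   annotators (default 0.6, i.e. raters mostly within one point of the
#'   clip consensus).
#' @param latent_means optional list with one numeric vector of clip latent
#'   means per scale; defaults to uniform draws on 1..5.
#' @param scales scale names.
#' @param seed RNG seed.
#' @return object of class `emorec_ratings`: a named list of
#'   annotators x clips integer matrices, one per scale, with annotator and
#'   clip ids in dimnames.
#' @examples
#' rt <- generate_ratings(27, 29, outlier_ids = c(4, 11), seed = 7)
#' dim(rt$valence)
#' @export
generate_ratings <- function(n_annotators, n_clips, outlier_ids = integer(),
                             noise_sd = 0.6, latent_means = NULL,
                             scales = c("valence", "arousal", "dominance",
                                        "liking", "familiarity"),
                             seed = NULL) {
  if (n_annotators < 3L) stop("need at least 3 annotators")
  if (n_clips < 2L) stop("invalid design: need at least 2 clips")
  outlier_ids <- as.integer(outlier_ids)
  if (length(outlier_ids) && (any(outlier_ids < 1L) ||
                              any(outlier_ids > n_annotators))) {
    stop("outlier_ids must be annotator indices")
  }
  with_seed(seed, {
    tabs <- lapply(scales, function(sc) {
      mu <- if (!is.null(latent_means)) latent_means[[sc]]
            else stats::runif(n_clips, 1, 5)
      if (length(mu) != n_clips) stop("latent_means length mismatch")
      raw <- matrix(
        rep(mu, each = n_annotators) +
          stats::rnorm(n_annotators * n_clips, 0, noise_sd),
        n_annotators, n_clips
      )
      m <- matrix(pmin(5L, pmax(1L, as.integer(round(raw)))),
                  n_annotators, n_clips)
      if (length(outlier_ids)) {
        m[outlier_ids, ] <- matrix(
          sample.int(5L, length(outlier_ids) * n_clips, replace = TRUE),
          length(outlier_ids), n_clips
        )
      }
      dimnames(m) <- list(paste0("a", seq_len(n_annotators)),
                          paste0("clip", seq_len(n_clips)))
      m
    })
    names(tabs) <- scales
    structure(tabs, class = "emorec_ratings",
              outlier_ids = outlier_ids, noise_sd = noise_sd)
  })
}

#' @export
print.emorec_ratings <- function(x, ...) {
  cat(sprintf("Rating table: %d annotators x %d clips, scales: %s\n",
              nrow(x[[1]]), ncol(x[[1]]), paste(names(x), collapse = ", ")))
  invisible(x)
}

#' Read or write rating tables as delimited text
#'
#' One tab-separated file per scale (`<scale>.tsv`), rows = annotators,
#' columns = clips.
#'
#' @param ratings an `emorec_ratings` object.
#' @param dir directory to write to / read from.
#' @param scales scales to read.
#' @return `write_ratings` returns the directory invisibly; `read_ratings`
#'   returns an `emorec_ratings` object.
#' @export
write_ratings <- function(ratings, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sc in names(ratings)) {
    utils::write.table(ratings[[sc]], file.path(dir, paste0(sc, ".tsv")),
                       sep = "\t", quote = FALSE, col.names = NA)
  }
  invisible(dir)
}

#' @rdname write_ratings
#' @export
read_ratings <- function(dir, scales = c("valence", "arousal", "dominance",
                                         "liking", "familiarity")) {
  tabs <- lapply(scales, function(sc) {
    f <- file.path(dir, paste0(sc, ".tsv"))
    if (!file.exists(f)) stop("missing rating file: ", f)
    as.matrix(utils::read.table(f, sep = "\t", header = TRUE,
                                row.names = 1, check.names = FALSE))
  })
  names(tabs) <- scales
  structure(tabs, class = "emorec_ratings")
}
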