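#' Emotion labels and session designs
#'
#' The study design works with five discrete emotions placed on the
#' valence-arousal plane: calmness (high valence, low arousal), happiness
#' (high valence, high arousal), and three negative emotions -- sadness,
#' fear and anger -- all low valence, high arousal. Three session designs
#' grow the emotion set cumulatively: session 1 uses calmness, fear and
#' happiness; session 2 adds sadness; session 3 further adds anger.
#'
#' @return `emotion_labels()` returns a data.frame with one row per emotion
#'   and columns `name`, `valence_class`, `arousal_class`.
#' @examples
#' emotion_labels()
#' session_design(3)
#' @export
emotion_labels <- function() {
  data.frame(
    name = c("calmness", "happiness", "sadness", "fear", "anger"),
    valence_class = c("high", "high", "low", "low", "low"),
    arousal_class = c("low", "high", "high", "high", "high"),
    stringsAsFactors = FALSE
  )
}

#' @rdname emotion_labels
#' @param emotions character vector of emotion names.
#' @return `negative_emotions()` returns the low-valence subset of
#'   `emotions` (in canonical order).
#' @export
negative_emotions <- function(emotions = emotion_labels()$name) {
  lab <- emotion_labels()
  low <- lab$name[lab$valence_class == "low"]
  intersect(emotions, low)
}

#' @rdname emotion_labels
#' @param session_id integer 1, 2 or 3.
#' @param n_subjects subjects recorded in the session (default 15).
#' @param trials_per_emotion trials recorded per subject and emotion.
#' @return `session_design()` returns an object of class
#'   `emorec_design`: a list with `session_id`, `emotions`, `n_subjects`
#'   and `trials_per_emotion`.
#' @export
session_design <- function(session_id, n_subjects = 15L,
                           trials_per_emotion = 2L) {
  if (!session_id %in% 1:3) {
    stop("session_id must be 1, 2 or 3")
  }
  emotions <- switch(session_id,
    c("calmness", "fear", "happiness"),
    c("calmness", "fear", "happiness", "sadness"),
    c("calmness", "fear", "happiness", "sadness", "anger")
  )
  if (n_subjects < 1L || trials_per_emotion < 1L) {
    stop("n_subjects and trials_per_emotion must be positive")
  }
  structure(
    list(
      session_id = as.integer(session_id),
      emotions = emotions,
      n_subjects = as.integer(n_subjects),
      trials_per_emotion = as.integer(trials_per_emotion)
    ),
    class = "emorec_design"
  )
}

#' @export
print.emorec_design <- function(x, ...) {
  cat(sprintf(
    "Session %d design: %d subjects, %d trial(s)/emotion\n  emotions: %s\n",
    x$session_id, x$n_subjects, x$trials_per_emotion,
    paste(x$emotions, collapse = ", ")
  ))
  invisible(x)
}

#' Default consensus affect scores per emotion
#'
#' Five-point consensus ratings assigned to each discrete emotion's clips,
#' used to split samples into positive/negative groups along a dimension.
#' High-class emotions sit above the midpoint 3, low-class below, matching
#' the quadrant each emotion occupies on the affect plane.
#'
#' @param dimension `"valence"` or `"arousal"`.
#' @return named numeric vector of consensus scores (1-5 scale).
#' @export
consensus_scores <- function(dimension = c("valence", "arousal")) {
  dimension <- match.arg(dimension)
  if (dimension == "valence") {
    c(calmness = 4.2, happiness = 4.5, sadness = 1.8, fear = 1.5,
      anger = 1.6)
  } else {
    c(calmness = 1.8, happiness = 4.0, sadness = 3.6, fear = 4.3,
      anger = 4.4)
  }
}
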