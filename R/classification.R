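#' Temporal block cross-validation splits
#'
#' Within each trial, samples are partitioned in temporal order into
#' `n_blocks` contiguous blocks; fold k tests on block k of every trial
#' and trains on the rest. Blocks are contiguous (not random) so that
#' temporally adjacent, autocorrelated samples never straddle the
#' train/test boundary more than once per fold.
#'
#' @param labels data.frame with columns `trial` and `order` (temporal
#'   index within trial) for one subject's samples.
#' @param n_blocks number of folds (default 5).
#' @return list of `n_blocks` elements, each `list(train, test)` integer
#'   row indices into `labels`.
#' @export
block_split <- function(labels, n_blocks = 5L) {
  trials <- unique(labels[, c("emotion", "trial")])
  fold_of <- integer(nrow(labels))
  for (r in seq_len(nrow(trials))) {
    idx <- which(labels$trial == trials$trial[r] &
                   labels$emotion == trials$emotion[r])
    idx <- idx[order(labels$order[idx])]
    if (length(idx) < n_blocks) {
      stop(sprintf("trial %s/%s has %d samples, fewer than %d blocks",
                   trials$emotion[r], trials$trial[r], length(idx),
                   n_blocks))
    }
    # contiguous near-equal blocks
    cuts <- floor(seq(0, length(idx), length.out = n_blocks + 1L))
    for (k in seq_len(n_blocks)) {
      fold_of[idx[(cuts[k] + 1L):cuts[k + 1L]]] <- k
    }
  }
  lapply(seq_len(n_blocks), function(k) {
    list(train = which(fold_of != k), test = which(fold_of == k))
  })
}

#' Subject-dependent linear-SVM evaluation under block cross-validation
#'
#' For each subject separately: split that subject's samples with
#' [block_split()], z-score every feature using training-fold statistics,
#' fit a linear support vector machine (cost `cost`), and classify the
#' held-out block; repeat over all folds. Reports the cross-average
#' accuracy over folds and subjects plus the pooled confusion matrix.
#' Columns that are constant in a training fold (zero variance) are left
#' unscaled; NA feature cells are imputed with the training-fold mean.
#'
#' @param dataset an `emorec_dataset`.
#' @param n_blocks folds (default 5).
#' @param cost SVM regularization constant (default 1).
#' @return object of class `emorec_cv`: list with `mean_accuracy`
#'   (percent), `per_subject` (percent per subject), `per_fold`
#'   (subject x fold matrix), `confusion` (true x predicted counts),
#'   `n_classes`.
#' @export
train_eval <- function(dataset, n_blocks = 5L, cost = 1) {
  labs <- dataset$labels
  classes <- sort(unique(labs$emotion))
  if (length(classes) < 2L) stop("need at least 2 classes")
  subjects <- sort(unique(labs$subject))
  conf <- matrix(0L, length(classes), length(classes),
                 dimnames = list(true = classes, predicted = classes))
  per_fold <- matrix(NA_real_, length(subjects), n_blocks,
                     dimnames = list(subjects, NULL))
  for (si in seq_along(subjects)) {
    rows <- which(labs$subject == subjects[si])
    sl <- labs[rows, , drop = FALSE]
    X <- dataset$features[rows, , drop = FALSE]
    y <- factor(sl$emotion, levels = classes)
    folds <- block_split(sl, n_blocks)
    for (k in seq_len(n_blocks)) {
      tr <- folds[[k]]$train
      te <- folds[[k]]$test
      if (length(unique(y[tr])) < 2L) {
        stop("degenerate single-class training fold")
      }
      mu <- colMeans(X[tr, , drop = FALSE], na.rm = TRUE)
      sdv <- apply(X[tr, , drop = FALSE], 2L, stats::sd, na.rm = TRUE)
      mu[!is.finite(mu)] <- 0
      sdv[!is.finite(sdv) | sdv == 0] <- 1
      zs <- function(M) {
        M <- sweep(M, 2L, mu, "-")
        M <- sweep(M, 2L, sdv, "/")
        M[!is.finite(M)] <- 0
        M
      }
      fit <- e1071::svm(zs(X[tr, , drop = FALSE]), y[tr],
                        kernel = "linear", cost = cost, scale = FALSE)
      pred <- stats::predict(fit, zs(X[te, , drop = FALSE]))
      per_fold[si, k] <- 100 * mean(pred == y[te])
      conf <- conf + unclass(table(y[te], pred))
    }
  }
  per_subject <- rowMeans(per_fold)
  structure(
    list(mean_accuracy = mean(per_subject), per_subject = per_subject,
         per_fold = per_fold, confusion = conf,
         n_classes = length(classes), modality = dataset$modality,
         session_id = dataset$design$session_id),
    class = "emorec_cv"
  )
}

#' @export
print.emorec_cv <- function(x, ...) {
  cat(sprintf(
    "Block-CV linear SVM (%s, session %s): mean accuracy %.2f%% over %d subjects, %d classes\n",
    x$modality %||% "?", x$session_id %||% "?", x$mean_accuracy,
    length(x$per_subject), x$n_classes
  ))
  invisible(x)
}

#' @export
summary.emorec_cv <- function(object, ...) {
  print(object)
  cat("Per-subject accuracy (%):\n")
  print(round(object$per_subject, 2))
  cat("Confusion matrix (true x predicted):\n")
  print(object$confusion)
  invisible(object)
}

#' Restrict a dataset to a subset of emotions
#'
#' Retains only samples whose label is in `keep`; all metadata preserved.
#' Used for the balanced comparison in which only the session-1 emotion
#' set is extracted from the larger sessions.
#'
#' @param dataset an `emorec_dataset`.
#' @param keep emotions to retain (must be a subset of the session's
#'   design).
#' @return filtered `emorec_dataset`.
#' @export
balanced_subset <- function(dataset, keep) {
  if (!all(keep %in% dataset$design$emotions)) {
    stop("keep must be a subset of the session's emotions")
  }
  rows <- dataset$labels$emotion %in% keep
  out <- dataset
  out$features <- dataset$features[rows, , drop = FALSE]
  out$labels <- dataset$labels[rows, , drop = FALSE]
  rownames(out$labels) <- NULL
  out
}

#' Per-session accuracy sweep with balanced-subset comparison
#'
#' Runs [train_eval()] on each session's full emotion set and, for the
#' sessions beyond the first, on the session-1 emotion subset; reports
#' the accuracy table, per-session confusion matrices, and Welch
#' two-sample t-tests comparing each later session's per-subject
#' subset accuracies against session 1.
#'
#' @param datasets list of `emorec_dataset`s, one per session, in
#'   session order.
#' @param n_blocks,cost passed to [train_eval()].
#' @return object of class `emorec_sweep`: list with `table` (data.frame:
#'   session, scope, n_classes, accuracy), `cv` (list of `emorec_cv`),
#'   `subset_tests` (list of `htest`).
#' @export
session_sweep <- function(datasets, n_blocks = 5L, cost = 1) {
  base_set <- datasets[[1]]$design$emotions
  runs <- list(); tab <- list()
  for (i in seq_along(datasets)) {
    cv <- train_eval(datasets[[i]], n_blocks, cost)
    key <- sprintf("session%d_full", datasets[[i]]$design$session_id)
    runs[[key]] <- cv
    tab[[length(tab) + 1L]] <- data.frame(
      session = datasets[[i]]$design$session_id, scope = "full",
      n_classes = cv$n_classes, accuracy = cv$mean_accuracy
    )
    if (i > 1L) {
      cv_sub <- train_eval(balanced_subset(datasets[[i]], base_set),
                           n_blocks, cost)
      key <- sprintf("session%d_subset", datasets[[i]]$design$session_id)
      runs[[key]] <- cv_sub
      tab[[length(tab) + 1L]] <- data.frame(
        session = datasets[[i]]$design$session_id, scope = "session1_subset",
        n_classes = cv_sub$n_classes, accuracy = cv_sub$mean_accuracy
      )
    }
  }
  tests <- list()
  for (i in seq_along(datasets)[-1]) {
    key <- sprintf("session%d_subset", datasets[[i]]$design$session_id)
    tests[[key]] <- tryCatch(
      stats::t.test(runs[[key]]$per_subject,
                    runs[["session1_full"]]$per_subject),
      error = function(e) NULL   # degenerate (constant) accuracies
    )
  }
  structure(list(table = do.call(rbind, tab), cv = runs,
                 subset_tests = tests,
                 modality = datasets[[1]]$modality),
            class = "emorec_sweep")
}

#' @export
print.emorec_sweep <- function(x, ...) {
  cat(sprintf("Session sweep (%s):\n", x$modality %||% "?"))
  print(x$table, row.names = FALSE)
  invisible(x)
}
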