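#' Per-frame predictions for a labelled segment
#'
#' The shared contract between the ConvNet and every baseline: one
#' probability vector per frame of a contiguous gesture segment, plus
#' the segment's true label and provenance.
#'
#' @param probs Matrix frames x G of class probabilities (rows sum to 1
#'   within tolerance); column names identify the classes (defaults to
#'   `1..G`).
#' @param label True gesture label of the segment.
#' @param subject,segment Identifiers used when aggregating accuracies.
#' @return An object of class `frame_predictions`.
#' @export
frame_predictions <- function(probs, label, subject = 1L, segment = 1L) {
  probs <- as.matrix(probs)
  if (any(probs < -1e-9) || any(abs(rowSums(probs) - 1) > 1e-6))
    stop("probs rows must be non-negative and sum to 1")
  if (is.null(colnames(probs))) colnames(probs) <- seq_len(ncol(probs))
  structure(list(probs = probs, label = label, subject = subject,
                 segment = segment),
            class = "frame_predictions")
}

pred_labels <- function(fp) {
  cls <- as.numeric(colnames(fp$probs))
  cls[max.col(fp$probs, ties.method = "first")]
}

#' Majority voting over trailing frame windows
#'
#' For each frame, the output label is the modal frame-level label in
#' the trailing window ending at that frame (windows are truncated at
#' the segment start, so the decision at frame t uses frames
#' `max(1, t-window+1) .. t`). Ties break to the smallest class label,
#' making the vote deterministic and order-independent.
#'
#' @param labels Integer vector of frame-level labels (non-empty).
#' @param window Window length in frames (>= 1); `Inf` votes over the
#'   whole sequence at every position.
#' @return Integer vector of voted labels, same length as `labels`.
#' @examples
#' majority_vote(c(2, 2, 3), 3)        # all 2
#' majority_vote(c(1, 1, 2, 2), 4)     # tie at t = 4 -> 1
#' @export
majority_vote <- function(labels, window) {
  n <- length(labels)
  if (n == 0L) stop("empty label sequence")
  stopifnot(window >= 1)
  if (window == 1) return(labels)
  cls <- sort(unique(labels))
  li <- match(labels, cls)
  counts <- integer(length(cls))
  out <- integer(n)
  for (t in seq_len(n)) {
    counts[li[t]] <- counts[li[t]] + 1L
    if (is.finite(window) && t > window) {
      drop <- li[t - window]
      counts[drop] <- counts[drop] - 1L
    }
    out[t] <- cls[which.max(counts)]   # first max = smallest class label
  }
  if (!is.finite(window)) out[] <- out[n]
  out
}

#' Pool two decision streams into one majority vote
#'
#' Votes over the concatenated frame decisions of two aligned streams
#' (e.g. T instantaneous-image decisions together with the T-1
#' difference-image decisions, a pool of 2T-1 votes). One stream may be
#' empty; the lengths may differ by at most one frame.
#'
#' @param labels_a,labels_b Integer frame-decision vectors.
#' @return The single voted label for the pooled segment.
#' @export
fuse_streams <- function(labels_a, labels_b) {
  if (length(labels_a) == 0L && length(labels_b) == 0L)
    stop("both streams empty")
  if (length(labels_a) > 0L && length(labels_b) > 0L &&
      abs(length(labels_a) - length(labels_b)) > 1L)
    stop("streams are misaligned")
  pooled <- c(labels_a, labels_b)
  mv <- majority_vote(pooled, length(pooled))
  mv[length(mv)]
}

#' Cross-validation splits over trials
#'
#' The three evaluation protocols, all deterministic from metadata:
#' `odd_even` trains on odd-numbered trials and tests on the rest;
#' `leave_one_trial_out` produces one fold per trial (per session when
#' session ids are given); `two_thirds` trains on the first
#' `ceiling(2N/3)` trials (pass `train_trials` to override with
#' published repetition indices).
#'
#' @param trials Integer vector of trial numbers (typically `1..N`).
#' @param protocol One of `"odd_even"`, `"leave_one_trial_out"`,
#'   `"two_thirds"`.
#' @param sessions Optional session id per trial; leave-one-trial-out
#'   then folds within each session.
#' @param train_trials Optional explicit training trial numbers for
#'   `two_thirds`.
#' @return List of folds, each `list(train = , test = )` of trial
#'   numbers; folds are disjoint and cover all trials.
#' @export
split_trials <- function(trials,
                         protocol = c("odd_even", "leave_one_trial_out",
                                      "two_thirds"),
                         sessions = NULL, train_trials = NULL) {
  protocol <- match.arg(protocol)
  if (protocol == "odd_even") {
    trials <- sort(unique(trials))
    odd <- trials[trials %% 2L == 1L]
    list(list(train = odd, test = setdiff(trials, odd)))
  } else if (protocol == "leave_one_trial_out") {
    if (is.null(sessions)) sessions <- rep(1L, length(trials))
    pairs <- unique(data.frame(trial = trials, session = sessions))
    folds <- list()
    for (s in unique(pairs$session)) {
      ts <- sort(pairs$trial[pairs$session == s])
      for (t in ts)
        folds[[length(folds) + 1L]] <- list(train = setdiff(ts, t),
                                            test = t, session = s)
    }
    folds
  } else {
    trials <- sort(unique(trials))
    if (is.null(train_trials))
      train_trials <- trials[seq_len(ceiling(2 * length(trials) / 3))]
    list(list(train = intersect(trials, train_trials),
              test = setdiff(trials, train_trials)))
  }
}

#' Recognition accuracy of frame predictions
#'
#' @param preds A `frame_predictions` or a list of them.
#' @param level `"frame"`: proportion of correctly recognised images;
#'   `"voted"`: correctness of trailing-window voted decisions
#'   (`window` frames); `"segment"`: one whole-segment vote per segment.
#' @param window Voting window for `level = "voted"`.
#' @return An object of class `vote_result`: a list with the window,
#'   per-subject accuracies, their mean and standard deviation.
#' @export
accuracy <- function(preds, level = c("frame", "voted", "segment"),
                     window = 1L) {
  level <- match.arg(level)
  w <- switch(level, frame = 1L, voted = window, segment = Inf)
  vote_result(preds, w, per_segment = (level == "segment"))
}

vote_result <- function(preds, window, per_segment = FALSE) {
  if (inherits(preds, "frame_predictions")) preds <- list(preds)
  subj <- vapply(preds, `[[`, numeric(1), "subject")
  acc_by_subject <- vapply(unique(subj), function(s) {
    ps <- preds[subj == s]
    scores <- lapply(ps, function(fp) {
      voted <- majority_vote(pred_labels(fp), window)
      if (per_segment) as.numeric(voted[length(voted)] == fp$label)
      else as.numeric(voted == fp$label)
    })
    mean(unlist(scores))
  }, numeric(1))
  structure(list(window = window, subjects = unique(subj),
                 per_subject = acc_by_subject,
                 mean = mean(acc_by_subject),
                 sd = stats::sd(acc_by_subject)),
            class = "vote_result")
}

#' @export
print.vote_result <- function(x, ...) {
  cat(sprintf("<vote_result> window %s: accuracy %.4f (sd %s, %d subject%s)\n",
              format(x$window), x$mean,
              if (is.na(x$sd)) "NA" else sprintf("%.4f", x$sd),
              length(x$subjects), if (length(x$subjects) > 1) "s" else ""))
  invisible(x)
}

#' Accuracy as a function of the voting window
#'
#' Recomputes the voted accuracy for each window length, reported as the
#' per-subject mean with its standard deviation across subjects; the
#' whole-segment vote is included via `Inf` in `windows`.
#'
#' @param preds List of `frame_predictions` (>= 1 segment).
#' @param windows Numeric vector of window lengths in frames; `Inf`
#'   means majority voting over the entire segment of each trial.
#' @return A data.frame with columns `window`, `accuracy`, `sd`; the
#'   full `vote_result` objects are attached as attribute `"results"`.
#' @export
vote_curve <- function(preds, windows = c(1, 40, 150, Inf)) {
  if (inherits(preds, "frame_predictions")) preds <- list(preds)
  if (length(preds) == 0L) stop("no segments supplied")
  seg_len <- vapply(preds, function(fp) nrow(fp$probs), numeric(1))
  finite_w <- windows[is.finite(windows)]
  if (length(finite_w) && any(finite_w > max(seg_len)))
    stop("a voting window exceeds every segment length")
  res <- lapply(windows, function(w)
    vote_result(preds, w, per_segment = !is.finite(w)))
  df <- data.frame(window = windows,
                   accuracy = vapply(res, `[[`, numeric(1), "mean"),
                   sd = vapply(res, `[[`, numeric(1), "sd"))
  attr(df, "results") <- res
  df
}
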