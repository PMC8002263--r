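#' Confusion counts at a decision threshold
#'
#' Scores at or above `threshold` are called CHF-positive (a tie at exactly
#' 0.5 is positive). TP/FN count CHF segments classified correctly/wrongly;
#' TN/FP count non-CHF segments.
#'
#' @param labels Binary vector, 1 = CHF.
#' @param scores Numeric prediction scores.
#' @param threshold Decision threshold, default 0.5.
#' @return Named integer vector with elements `TP`, `FP`, `TN`, `FN`.
#' @examples
#' confusion_counts(c(1, 1, 0, 0), c(0.9, 0.2, 0.1, 0.8))
#' @export
confusion_counts <- function(labels, scores, threshold = 0.5) {
  if (!length(labels) || length(labels) != length(scores))
    stop_invalid("labels and scores must be non-empty and of equal length")
  if (!all(labels %in% c(0, 1))) stop_invalid("labels must be binary")
  pred <- as.integer(scores >= threshold)
  c(TP = sum(pred == 1 & labels == 1),
    FP = sum(pred == 1 & labels == 0),
    TN = sum(pred == 0 & labels == 0),
    FN = sum(pred == 0 & labels == 1))
}

#' Classification metrics from confusion counts
#'
#' Accuracy `(TP+TN)/n`, recall `TP/(TP+FN)`, precision `TP/(TP+FP)` and the
#' F1 score (harmonic mean of precision and recall). A metric whose
#' denominator is zero is reported as 0, as is F1 when either component is 0.
#'
#' @param cc Confusion counts as returned by [confusion_counts()].
#' @return Named numeric vector `accuracy`, `recall`, `precision`, `f1`.
#' @examples
#' classification_metrics(c(TP = 3, FP = 1, TN = 4, FN = 2))
#' @export
classification_metrics <- function(cc) {
  n <- sum(cc)
  if (n == 0) stop_invalid("all confusion counts are zero")
  rec <- if (cc[["TP"]] + cc[["FN"]] > 0)
    cc[["TP"]] / (cc[["TP"]] + cc[["FN"]]) else 0
  prec <- if (cc[["TP"]] + cc[["FP"]] > 0)
    cc[["TP"]] / (cc[["TP"]] + cc[["FP"]]) else 0
  f1 <- if (prec > 0 && rec > 0) 2 * prec * rec / (prec + rec) else 0
  c(accuracy = (cc[["TP"]] + cc[["TN"]]) / n,
    recall = rec, precision = prec, f1 = f1)
}

#' ROC curve and area under it
#'
#' Sweeps the decision threshold over the distinct scores (ties grouped),
#' yielding a monotone step curve from (0, 0) to (1, 1) in (FPR, TPR)
#' space; the area is accumulated by the trapezoidal rule, which makes it
#' equal to the probability that a random positive outscores a random
#' negative, with ties counted half.
#'
#' @param labels Binary vector, 1 = positive; both classes must be present.
#' @param scores Numeric scores, larger = more positive.
#' @return List with `roc` (data.frame `fpr`, `tpr`, `threshold`) and
#'   scalar `auc`.
#' @examples
#' roc_auc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8))$auc
#' @export
roc_auc <- function(labels, scores) {
  if (!length(labels) || length(labels) != length(scores))
    stop_invalid("labels and scores must be non-empty and of equal length")
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0)
    stop_invalid("ROC needs both classes present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # cumulative counts at the end of every tie group
  grp_end <- which(c(diff(s) != 0, TRUE))
  ctp <- cumsum(y == 1)[grp_end]
  cfp <- cumsum(y == 0)[grp_end]
  roc <- data.frame(fpr = c(0, cfp / n_neg), tpr = c(0, ctp / n_pos),
                    threshold = c(Inf, s[grp_end]))
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) +
                              utils::tail(roc$tpr, -1)) / 2)
  list(roc = roc, auc = auc)
}

#' Subject-wise k-fold partition
#'
#' Splits subjects (never individual segments) into `k` parts of as-equal
#' size as possible using a seeded permutation, so that all segments of one
#' subject land in the same part — the inter-patient evaluation hygiene that
#' prevents within-subject leakage. For each fold, one part is the test
#' set; a fraction of the remaining subjects (at least one per class when
#' possible, when `labels` are supplied) is held out as the inner
#' validation set driving the learning-rate plateau schedule; the rest
#' train.
#'
#' @param subject_ids Character vector of unique subject ids.
#' @param k Number of folds, `2 <= k <= length(subject_ids)`.
#' @param seed RNG seed for the permutation.
#' @param val_fraction Fraction of training subjects carved out as inner
#'   validation (default 0.1).
#' @param labels Optional named vector (by subject id) of binary labels used
#'   to keep at least one subject per class in the validation set.
#' @return List of class `fold_split`: `parts` (list of k character
#'   vectors) and `folds` (list of k lists with `train`, `validation`,
#'   `test`).
#' @examples
#' subject_wise_kfold(sprintf("s%02d", 1:20), k = 10, seed = 1)$parts
#' @export
subject_wise_kfold <- function(subject_ids, k = 10L, seed = 1L,
                               val_fraction = 0.1, labels = NULL) {
  subject_ids <- as.character(subject_ids)
  if (anyDuplicated(subject_ids)) stop_invalid("subject ids must be unique")
  n <- length(subject_ids)
  if (k < 2 || k > n)
    stop_invalid("need 2 <= k <= number of subjects (", n, "), got k = ", k)
  with_seed(seed, {
    perm <- sample(subject_ids)
    part_of <- rep(seq_len(k), length.out = n)  # sizes differ by at most 1
    parts <- split(perm, part_of)
    names(parts) <- NULL
    folds <- lapply(seq_len(k), function(f) {
      test <- parts[[f]]
      rest <- unlist(parts[-f], use.names = FALSE)
      val <- pick_validation(rest, val_fraction, labels)
      list(train = setdiff(rest, val), validation = val, test = test)
    })
    structure(list(parts = parts, folds = folds, k = k), class = "fold_split")
  })
}

pick_validation <- function(rest, val_fraction, labels) {
  n_val <- max(1L, floor(val_fraction * length(rest)))
  if (is.null(labels)) return(sample(rest, n_val))
  cls <- labels[rest]
  val <- character(0)
  for (cl in unique(cls)) {          # >= 1 subject per class when possible
    members <- rest[cls == cl]
    take <- max(1L, round(n_val * sum(cls == cl) / length(rest)))
    val <- c(val, sample(members, min(take, length(members))))
  }
  unique(val)
}

#' Plateau learning-rate schedule
#'
#' The learning rate is multiplied by `factor` whenever the best validation
#' loss seen so far has not improved for `patience` consecutive epochs; the
#' patience counter then resets. `lr_schedule_step()` applies one epoch's
#' decision; `plateau_schedule()` replays a whole loss history and returns
#' the learning rate after each epoch.
#'
#' @param history Numeric vector of validation losses, oldest first, up to
#'   and including the current epoch.
#' @param current_lr Learning rate in force.
#' @param factor Multiplicative decay (default 0.1).
#' @param patience Epochs without improvement tolerated (default 5).
#' @param state Optional scheduler state from a previous call; when `NULL`
#'   it is reconstructed from `history`.
#' @return `lr_schedule_step()`: list `lr`, `state`. `plateau_schedule()`:
#'   numeric vector of per-epoch learning rates.
#' @examples
#' plateau_schedule(c(1, rep(1, 10)), 1e-4)  # two plateaus: 1e-5 then 1e-6
#' @export
lr_schedule_step <- function(history, current_lr, factor = 0.1,
                             patience = 5L, state = NULL) {
  if (!length(history)) stop_invalid("history must be non-empty")
  if (is.null(state)) {
    lr <- current_lr
    st <- list(best = Inf, wait = 0L)
    for (loss in history) {
      res <- schedule_advance(loss, lr, st, factor, patience)
      lr <- res$lr; st <- res$state
    }
    return(list(lr = lr, state = st))
  }
  res <- schedule_advance(history[length(history)], current_lr, state,
                          factor, patience)
  list(lr = res$lr, state = res$state)
}

schedule_advance <- function(loss, lr, st, factor, patience) {
  if (loss < st$best) {
    st$best <- loss
    st$wait <- 0L
  } else {
    st$wait <- st$wait + 1L
    if (st$wait >= patience) {
      lr <- lr * factor
      st$wait <- 0L
    }
  }
  list(lr = lr, state = st)
}

#' @rdname lr_schedule_step
#' @param initial_lr Learning rate before the first epoch.
#' @export
plateau_schedule <- function(history, initial_lr, factor = 0.1,
                             patience = 5L) {
  lr <- initial_lr
  st <- list(best = Inf, wait = 0L)
  out <- numeric(length(history))
  for (e in seq_along(history)) {
    res <- schedule_advance(history[e], lr, st, factor, patience)
    lr <- res$lr; st <- res$state
    out[e] <- lr
  }
  out
}
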