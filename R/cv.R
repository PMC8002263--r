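# Subject-wise cross-validation of the full pipeline.

segments_subset <- function(ds, subjects) {
  keep <- ds$subject %in% subjects
  out <- ds
  out$values <- ds$values[keep, , drop = FALSE]
  out$padded <- ds$padded[keep, , drop = FALSE]
  out$subject <- ds$subject[keep]
  out$cohort <- ds$cohort[keep]
  out$label <- ds$label[keep]
  out
}

#' Subject-wise k-fold cross-validation of the CHF classifier
#'
#' Splits subjects into `k` parts, trains one model per fold on the
#' remaining parts (with an inner validation subject subset driving the
#' learning-rate plateau schedule) and evaluates on the untouched test
#' part. No subject ever contributes segments to both sides of a fold;
#' this is verified programmatically on every run.
#'
#' @param segments An `rr_segments` object covering the whole cohort.
#' @param k Number of folds.
#' @param net A [network_config()].
#' @param train A [train_config()]; `train$seed` also seeds the fold split.
#' @param val_fraction Fraction of training subjects held out as inner
#'   validation.
#' @param threshold Decision threshold for the confusion counts.
#' @param keep_models If `TRUE`, the fitted per-fold models are kept in the
#'   report (under `folds[[f]]$model`), e.g. for checkpointing.
#' @return An object of class `chfnet_cv` with per-fold results (`folds`:
#'   confusion counts, metrics, ROC, AUC, training history) and pooled
#'   results over the concatenated test scores (`pooled`), plus
#'   `metrics_table`, a per-fold + pooled summary data.frame.
#' @examples
#' \donttest{
#' coh <- generate_cohort(n_per_class = 5, n_beats = 300, seed = 1)
#' ds <- build_dataset(coh, n = 64, depth = 2)
#' cv <- cv_chfnet(ds, k = 2, net = network_config(2, c(4, 8, 16)),
#'                 train = train_config(epochs = 2, initial_lr = 1e-3))
#' cv$pooled$metrics
#' }
#' @export
cv_chfnet <- function(segments, k = 10L, net = network_config(),
                      train = train_config(), val_fraction = 0.1,
                      threshold = 0.5, keep_models = FALSE) {
  stopifnot(inherits(segments, "rr_segments"))
  subjects <- unique(segments$subject)
  subj_label <- vapply(split(segments$label, segments$subject),
                       function(l) l[1], numeric(1))[subjects]
  if (length(unique(segments$label)) < 2)
    stop_invalid("cohort must contain both classes")
  split <- subject_wise_kfold(subjects, k = k, seed = train$seed,
                              val_fraction = val_fraction,
                              labels = subj_label)
  folds <- vector("list", k)
  pooled_scores <- numeric(0); pooled_labels <- integer(0)
  for (f in seq_len(k)) {
    fd <- split$folds[[f]]
    if (length(intersect(c(fd$train, fd$validation), fd$test)))
      stop("internal error: subject leakage between train and test")
    tr_seg <- segments_subset(segments, fd$train)
    va_seg <- segments_subset(segments, fd$validation)
    te_seg <- segments_subset(segments, fd$test)
    fold_train <- train
    fold_train$seed <- derive_seed(train$seed, f)
    fit <- chf_unetpp(tr_seg,
                      validation = if (nrow(va_seg$padded)) va_seg,
                      net = net, train = fold_train)
    scores <- predict(fit, te_seg)
    cc <- confusion_counts(te_seg$label, scores, threshold)
    ra <- tryCatch(roc_auc(te_seg$label, scores),
                   error = function(e) list(roc = NULL, auc = NA_real_))
    folds[[f]] <- list(
      subjects = fd, confusion = cc,
      metrics = classification_metrics(cc),
      roc = ra$roc, auc = ra$auc,
      history = fit$history, scores = scores, labels = te_seg$label,
      model = if (keep_models) fit)
    pooled_scores <- c(pooled_scores, scores)
    pooled_labels <- c(pooled_labels, te_seg$label)
  }
  cc_pool <- Reduce(`+`, lapply(folds, `[[`, "confusion"))
  ra_pool <- roc_auc(pooled_labels, pooled_scores)
  pooled <- list(confusion = cc_pool,
                 metrics = classification_metrics(cc_pool),
                 roc = ra_pool$roc, auc = ra_pool$auc,
                 scores = pooled_scores, labels = pooled_labels)
  mt <- do.call(rbind, lapply(seq_len(k), function(f) {
    data.frame(fold = as.character(f), t(folds[[f]]$metrics),
               auc = folds[[f]]$auc)
  }))
  mt <- rbind(mt, data.frame(fold = "pooled", t(pooled$metrics),
                             auc = pooled$auc))
  structure(list(folds = folds, pooled = pooled, metrics_table = mt,
                 k = k, net = net, train = train, split = split),
            class = "chfnet_cv")
}

#' @export
print.chfnet_cv <- function(x, ...) {
  cat(sprintf("Subject-wise %d-fold cross-validation (%s blocks)\n",
              x$k, x$net$block))
  cc <- x$pooled$confusion
  cat(sprintf("Pooled confusion: TP %d FP %d TN %d FN %d\n",
              cc[["TP"]], cc[["FP"]], cc[["TN"]], cc[["FN"]]))
  m <- x$pooled$metrics
  cat(sprintf(
    "Pooled: accuracy %.4f recall %.4f precision %.4f F1 %.4f AUC %.4f\n",
    m[["accuracy"]], m[["recall"]], m[["precision"]], m[["f1"]],
    x$pooled$auc))
  invisible(x)
}

#' @export
summary.chfnet_cv <- function(object, ...) {
  print(object)
  accs <- vapply(object$folds, function(f) f$metrics[["accuracy"]],
                 numeric(1))
  aucs <- vapply(object$folds, function(f) f$auc, numeric(1))
  cat(sprintf("Across folds: accuracy %.4f +/- %.4f, AUC %.4f +/- %.4f\n",
              mean(accs), stats::sd(accs), mean(aucs, na.rm = TRUE),
              stats::sd(aucs, na.rm = TRUE)))
  cat("\nPer-fold metrics:\n")
  print(object$metrics_table, row.names = FALSE, digits = 4)
  invisible(object)
}

#' @export
plot.chfnet_cv <- function(x, which = c("roc", "folds"), ...) {
  which <- match.arg(which)
  if (which == "roc") {
    r <- x$pooled$roc
    graphics::plot(r$fpr, r$tpr, type = "s", xlab = "false positive rate",
                   ylab = "true positive rate",
                   main = sprintf("Pooled ROC (AUC %.3f)", x$pooled$auc), ...)
    graphics::abline(0, 1, lty = 3)
  } else {
    graphics::plot(NULL, xlim = c(0, 1), ylim = c(0, 1),
                   xlab = "false positive rate", ylab = "true positive rate",
                   main = "Per-fold ROC", ...)
    for (f in seq_along(x$folds)) {
      r <- x$folds[[f]]$roc
      if (!is.null(r)) graphics::lines(r$fpr, r$tpr, type = "s", col = f)
    }
    graphics::abline(0, 1, lty = 3)
  }
  invisible(x)
}
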