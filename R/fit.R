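#' Training configuration
#'
#' Optimization hyperparameters. The defaults are the full-scale training
#' protocol: Adam, minibatches of 16, 70 epochs, initial learning rate
#' 1e-4, and a plateau schedule that multiplies the rate by 0.1 when the
#' validation loss has not improved for 5 epochs.
#'
#' @param batch_size Minibatch size.
#' @param epochs Training epochs.
#' @param initial_lr Initial Adam learning rate.
#' @param plateau_factor Multiplicative learning-rate decay on plateau.
#' @param plateau_patience Epochs without improvement before decaying.
#' @param balance_classes If `TRUE`, gradient contributions are reweighted
#'   inversely to class frequency. Off by default, matching the unweighted
#'   full-scale protocol.
#' @param seed Seed controlling initialization and epoch shuffling.
#' @return A list of class `train_config`.
#' @export
train_config <- function(batch_size = 16L, epochs = 70L, initial_lr = 1e-4,
                         plateau_factor = 0.1, plateau_patience = 5L,
                         balance_classes = FALSE, seed = 1L) {
  if (batch_size < 1 || epochs < 0 || initial_lr <= 0 ||
      plateau_factor <= 0 || plateau_factor >= 1 || plateau_patience < 1)
    stop_invalid("invalid training configuration")
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), initial_lr = initial_lr,
                 plateau_factor = plateau_factor,
                 plateau_patience = as.integer(plateau_patience),
                 balance_classes = isTRUE(balance_classes),
                 seed = as.integer(seed)),
            class = "train_config")
}

## ---- Adam ----

adam_init <- function() list(t = 0L, m = list(), v = list())

adam_step <- function(model, grads, opt, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  upd <- function(p, g, key) {
    m <- opt$m[[key]] %||% (g * 0)
    v <- opt$v[[key]] %||% (g * 0)
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    opt$m[[key]] <<- m
    opt$v[[key]] <<- v
    p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
  }
  for (bk in names(grads)) {
    if (bk == "head") next
    for (pn in names(grads[[bk]])) {
      key <- paste(bk, pn, sep = ".")
      model$blocks[[bk]][[pn]] <-
        upd(model$blocks[[bk]][[pn]], grads[[bk]][[pn]], key)
    }
  }
  model$head$W <- upd(model$head$W, grads$head$W, "head.W")
  model$head$b <- upd(model$head$b, grads$head$b, "head.b")
  list(model = model, opt = opt)
}

#' Fit the 1-D UNet++ CHF classifier
#'
#' Trains the nested encoder-decoder on labelled, padded RR segments with
#' Adam on the mean-squared-error objective. Segments are shuffled each
#' epoch; the learning rate follows the plateau schedule driven by the
#' validation loss (the training loss when no validation set is given).
#' The run is fully reproducible from `train$seed`.
#'
#' @param segments An `rr_segments` design object from [build_dataset()],
#'   containing both classes.
#' @param validation Optional `rr_segments` held-out set for the schedule
#'   and per-epoch monitoring.
#' @param net A [network_config()].
#' @param train A [train_config()].
#' @return An object of class `chf_unetpp`: the trained model with the
#'   per-epoch `history` (data.frame of train/validation loss and accuracy
#'   and the learning rate) and both configurations.
#' @examples
#' \donttest{
#' coh <- generate_cohort(n_per_class = 4, n_beats = 300, seed = 1)
#' ds <- build_dataset(coh, n = 64)
#' cfg <- network_config(depth = 2, channels = c(4, 8, 16))
#' fit <- chf_unetpp(ds, net = cfg,
#'                   train = train_config(epochs = 2, initial_lr = 1e-3))
#' predict(fit, ds)[1:3]
#' }
#' @export
chf_unetpp <- function(segments, validation = NULL,
                       net = network_config(), train = train_config()) {
  stopifnot(inherits(segments, "rr_segments"))
  X <- segments$padded; y <- segments$label
  if (nrow(X) == 0) stop_invalid("no training segments")
  if (length(unique(y)) < 2)
    stop_invalid("training set must contain both classes")
  if (segments$depth != net$depth)
    stop_invalid("segments were padded for depth ", segments$depth,
                 " but the network has depth ", net$depth)

  model <- network_init(net, seed = train$seed)
  sample_w <- NULL
  if (train$balance_classes) {
    freq <- table(factor(y, levels = 0:1)) / length(y)
    sample_w <- as.numeric(0.5 / freq[as.character(y)])
  }
  opt <- adam_init()
  lr <- train$initial_lr
  sched <- list(best = Inf, wait = 0L)
  hist <- data.frame(epoch = integer(0), lr = numeric(0),
                     train_loss = numeric(0), train_acc = numeric(0),
                     val_loss = numeric(0), val_acc = numeric(0))

  with_seed(train$seed, {
    for (epoch in seq_len(train$epochs)) {
      ord <- sample(nrow(X))
      for (start in seq(1, nrow(X), by = train$batch_size)) {
        idx <- ord[start:min(start + train$batch_size - 1L, nrow(X))]
        fwd <- network_forward(model, X[idx, , drop = FALSE],
                               training = TRUE)
        model <- fwd$model
        grads <- network_backward(model, fwd, y[idx], sample_w[idx])
        st <- adam_step(model, grads, opt, lr)
        model <- st$model; opt <- st$opt
      }
      model <- finalize_bn_stats(model, X)
      tr <- evaluate_scores(model, X, y)
      if (!is.null(validation)) {
        va <- evaluate_scores(model, validation$padded, validation$label)
      } else {
        va <- tr
      }
      res <- schedule_advance(va$loss, lr, sched,
                              train$plateau_factor, train$plateau_patience)
      lr <- res$lr; sched <- res$state
      hist[epoch, ] <- list(epoch, lr, tr$loss, tr$acc, va$loss, va$acc)
    }
  })

  structure(list(model = model, net = net, train = train, history = hist,
                 n = segments$n, m = segments$m,
                 classes = table(factor(y, levels = 0:1))),
            class = "chf_unetpp")
}

# Replace the exponentially smoothed batch-norm running statistics with the
# exact activation statistics over the training set (one extra pass,
# running-averaged across batches). Keeps evaluation-mode scores consistent
# with training-mode behaviour even after very short training runs.
finalize_bn_stats <- function(model, X, batch = 128L) {
  i <- 0L
  for (start in seq(1, nrow(X), by = batch)) {
    i <- i + 1L
    idx <- start:min(start + batch - 1L, nrow(X))
    fwd <- network_forward(model, X[idx, , drop = FALSE], training = TRUE,
                           keep_cache = FALSE, bn_momentum = 1 / i)
    model <- fwd$model
  }
  model
}

evaluate_scores <- function(model, X, y, batch = 64L) {
  p <- predict_scores(model, X, batch)
  list(loss = mse_loss(y, p), acc = mean((p >= 0.5) == (y == 1)),
       scores = p)
}

predict_scores <- function(model, X, batch = 64L) {
  p <- numeric(nrow(X))
  for (start in seq(1, nrow(X), by = batch)) {
    idx <- start:min(start + batch - 1L, nrow(X))
    fwd <- network_forward(model, X[idx, , drop = FALSE],
                           training = FALSE, keep_cache = FALSE)
    p[idx] <- fwd$scores
  }
  p
}

#' @export
print.chf_unetpp <- function(x, ...) {
  cat(sprintf(
    "1-D UNet++ CHF classifier (%s blocks, depth %d, channels %s)\n",
    x$net$block, x$net$depth, paste(x$net$channels, collapse = "-")))
  cat(sprintf("Trained %d epochs on %d segments (CHF %d / non-CHF %d), n = %d (padded %d)\n",
              nrow(x$history), sum(x$classes), x$classes[["1"]],
              x$classes[["0"]], x$n, x$m))
  if (nrow(x$history)) {
    h <- x$history[nrow(x$history), ]
    cat(sprintf(
      "Final epoch: train loss %.4f acc %.3f | val loss %.4f acc %.3f | lr %.2g\n",
      h$train_loss, h$train_acc, h$val_loss, h$val_acc, h$lr))
  }
  invisible(x)
}

#' @export
summary.chf_unetpp <- function(object, ...) {
  print(object)
  n_par <- sum(vapply(object$model$blocks, function(b) {
    sum(vapply(block_param_names(b), function(nm) length(b[[nm]]),
               numeric(1)))
  }, numeric(1))) + length(object$model$head$W) + 1
  cat(sprintf("Trainable parameters: %d\n", as.integer(n_par)))
  if (nrow(object$history)) {
    cat("Best validation epoch:",
        which.min(object$history$val_loss), "\n")
  }
  invisible(object)
}

#' Predict CHF scores for RR segments
#'
#' @param object A fitted [chf_unetpp()] model.
#' @param newdata An `rr_segments` object or a numeric matrix of padded
#'   segments (one row each, length matching the model input).
#' @param type `"score"` for the logistic output in `[0, 1]`, `"class"` for
#'   the thresholded 0/1 decision.
#' @param threshold Decision threshold for `type = "class"`.
#' @param ... Unused.
#' @return Numeric vector of scores or integer class labels.
#' @export
predict.chf_unetpp <- function(object, newdata, type = c("score", "class"),
                               threshold = 0.5, ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "rr_segments")) newdata$padded else
    as.matrix(newdata)
  p <- predict_scores(object$model, X)
  if (type == "score") p else as.integer(p >= threshold)
}

#' @export
residuals.chf_unetpp <- function(object, newdata, ...) {
  if (missing(newdata) || !inherits(newdata, "rr_segments"))
    stop_invalid("residuals need an rr_segments object with labels")
  newdata$label - predict(object, newdata)
}

#' @export
plot.chf_unetpp <- function(x, which = c("loss", "accuracy"), ...) {
  which <- match.arg(which)
  h <- x$history
  if (!nrow(h)) stop_invalid("no training history to plot")
  if (which == "loss") {
    graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                      lty = 1:2, col = c("black", "red"),
                      xlab = "epoch", ylab = "MSE loss", ...)
    graphics::legend("topright", c("train", "validation"),
                     lty = 1:2, col = c("black", "red"), bty = "n")
  } else {
    graphics::matplot(h$epoch, cbind(h$train_acc, h$val_acc), type = "l",
                      lty = 1:2, col = c("black", "red"),
                      xlab = "epoch", ylab = "accuracy", ...)
    graphics::legend("bottomright", c("train", "validation"),
                     lty = 1:2, col = c("black", "red"), bty = "n")
  }
  invisible(x)
}
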