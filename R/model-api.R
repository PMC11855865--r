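# User-facing model API: training with early stopping, risk prediction,
# and threshold-based evaluation.

#' Train a risk model on encoded sequences
#'
#' Fits one of the four model families on the training split, monitoring
#' AUROC on the validation split after every epoch and stopping once it has
#' not improved for `config$patience` epochs (the best-epoch weights are
#' kept). All model families — including logistic regression on the binary
#' bag-of-codes — share the same Adam optimizer and early-stopping harness,
#' so `patience` and `seed` mean the same thing everywhere. The
#' max-F1 decision threshold is chosen on the validation split and frozen
#' into the model before any test data is seen.
#'
#' @param train,val `encoded_cohort` tibbles (both must contain both
#'   classes). Samples with no visits are dropped from training with a
#'   warning.
#' @param config A [model_config()].
#' @return An object of class `ehrisk_model`: parameters, config, training
#'   `history` (per-epoch train loss and validation AUROC), `stopped_epoch`,
#'   `best_epoch`, frozen `threshold`, and the training-split base rate.
#' @export
train_risk_model <- function(train, val, config = model_config()) {
  kind <- config$model_kind
  vocab <- attr(train, "vocab")
  V <- if (!is.null(vocab)) vocab_size(vocab) else
    max(unlist(c(train$visits, val$visits), use.names = FALSE))
  if (V > config$vocab_cap) {
    abort(sprintf("vocabulary size %d exceeds vocab_cap %d.", V, config$vocab_cap))
  }
  for (nm in c("train", "val")) {
    s <- get(nm)
    if (!nrow(s)) abort(sprintf("`%s` split is empty.", nm))
    if (length(unique(s$label)) < 2L) {
      abort(sprintf("`%s` split contains a single class; cannot train.", nm))
    }
  }
  keep <- lengths(train$visits) > 0L
  if (!all(keep)) {
    warn(sprintf("dropping %d training sample(s) with empty sequences.", sum(!keep)))
    train <- train[keep, ]
  }

  fit <- withr::with_seed(config$seed, {
    p <- nn_init_params(kind, V, config)
    state <- adam_init(p)
    n <- nrow(train)
    best <- list(auroc = -Inf, p = p, epoch = 0L)
    history <- list()
    stale <- 0L
    epoch <- 0L
    while (epoch < config$max_epochs) {
      epoch <- epoch + 1L
      ord <- sample.int(n)
      losses <- numeric(0)
      for (start in seq(1L, n, by = config$batch_size)) {
        rows <- ord[start:min(start + config$batch_size - 1L, n)]
        if (kind == "LR") {
          X <- lr_features(train$visits[rows], V)
          lg <- lr_loss_and_grads(p, X, as.numeric(train$label[rows]))
        } else {
          batch <- nn_make_batch(train$visits[rows], train$delta[rows],
                                 train$label[rows], reverse = kind == "RETAIN")
          lg <- nn_loss_and_grads(kind, p, batch, config, train_dropout = TRUE)
        }
        upd <- adam_step(p, lg$grads, state, config$learning_rate,
                         config$weight_decay)
        p <- upd$p
        state <- upd$state
        if (config$l1_embedding > 0) {
          p <- prox_group_l1(p, config$learning_rate, config$l1_embedding)
        }
        losses <- c(losses, lg$loss)
      }
      val_scores <- predict_scores(kind, p, val, config, V)
      val_auroc <- auroc(val_scores, val$label)
      history[[epoch]] <- tibble(epoch = epoch, train_loss = mean(losses),
                                 val_auroc = val_auroc)
      if (val_auroc > best$auroc + 1e-6) {
        best <- list(auroc = val_auroc, p = p, epoch = epoch)
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= config$patience) break
      }
    }
    list(p = best$p, best_epoch = best$epoch, stopped_epoch = epoch,
         history = bind_rows(history))
  })

  model <- structure(list(
    model_kind = kind,
    params = fit$p,
    vocab = vocab,
    vocab_size = V,
    config = config,
    history = fit$history,
    stopped_epoch = fit$stopped_epoch,
    best_epoch = fit$best_epoch,
    base_rate = mean(train$label),
    threshold = NA_real_
  ), class = "ehrisk_model")
  val_probs <- predict_risk(model, val)
  model$threshold <- max_f1_threshold(val_probs, val$label)
  model
}

predict_scores <- function(kind, p, samples, config, V, chunk = 2048L) {
  n <- nrow(samples)
  out <- numeric(n)
  nonempty <- which(lengths(samples$visits) > 0L)
  empty <- setdiff(seq_len(n), nonempty)
  if (length(empty)) out[empty] <- NA_real_
  for (start in seq(1L, length(nonempty), by = chunk)) {
    rows <- nonempty[start:min(start + chunk - 1L, length(nonempty))]
    if (!length(rows)) break
    if (kind == "LR") {
      X <- lr_features(samples$visits[rows], V)
      out[rows] <- lr_forward(p, X)
    } else {
      batch <- nn_make_batch(samples$visits[rows], samples$delta[rows],
                             rep(0, length(rows)), reverse = kind == "RETAIN")
      out[rows] <- nn_forward(kind, p, batch, config, train_dropout = FALSE)$z
    }
  }
  out
}

#' Predict 90-day outcome probabilities
#'
#' Empty sequences (no visits) receive the training base rate; the returned
#' vector carries an `empty_sequence` attribute flagging those positions.
#'
#' @param model An `ehrisk_model`.
#' @param samples An `encoded_cohort` tibble encoded with the model's
#'   vocabulary.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_risk <- function(model, samples) {
  z <- predict_scores(model$model_kind, model$params, samples, model$config,
                      model$vocab_size)
  empty <- is.na(z)
  probs <- sigmoid(z)
  probs[empty] <- model$base_rate
  attr(probs, "empty_sequence") <- which(empty)
  probs
}

max_f1_threshold <- function(probs, labels) {
  cand <- sort(unique(probs))
  if (length(cand) > 200L) cand <- quantile(probs, seq(0, 1, length.out = 200L),
                                            names = FALSE)
  f1s <- vapply(cand, function(th) {
    pred <- as.integer(probs >= th)
    tp <- sum(pred == 1L & labels == 1L)
    if (tp == 0L) return(0)
    prec <- tp / sum(pred == 1L)
    rec <- tp / sum(labels == 1L)
    2 * prec * rec / (prec + rec)
  }, numeric(1))
  cand[which.max(f1s)]
}

#' Evaluate a fitted model on a test split
#'
#' AUROC by the tie-aware rank statistic; precision, recall and F1 at the
#' decision threshold frozen on the validation split at training time.
#'
#' @param model An `ehrisk_model`.
#' @param test An `encoded_cohort` with both classes present.
#' @return A tibble of class `ehrisk_eval` with one row: `model_kind, auroc,
#'   precision, recall, f1, threshold, n_cases, n_controls`.
#' @export
evaluate_model <- function(model, test) {
  if (length(unique(test$label)) < 2L) {
    abort("test set contains a single class; AUROC is undefined.")
  }
  probs <- predict_risk(model, test)
  th <- model$threshold
  pred <- as.integer(probs >= th)
  tp <- sum(pred == 1L & test$label == 1L)
  fp <- sum(pred == 1L & test$label == 0L)
  fn <- sum(pred == 0L & test$label == 1L)
  prec <- if (tp + fp > 0L) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0L) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0) {
    2 * prec * rec / (prec + rec)
  } else 0
  out <- tibble(
    model_kind = model$model_kind,
    auroc = auroc(probs, test$label),
    precision = prec, recall = rec, f1 = f1,
    threshold = th,
    n_cases = sum(test$label == 1L),
    n_controls = sum(test$label == 0L)
  )
  class(out) <- c("ehrisk_eval", class(out))
  out
}

#' @export
print.ehrisk_model <- function(x, ...) {
  cat("<ehrisk_model> ", x$model_kind,
      " | vocab ", x$vocab_size,
      " | stopped at epoch ", x$stopped_epoch,
      " (best ", x$best_epoch, ", val AUROC ",
      sprintf("%.3f", max(x$history$val_auroc)), ")\n", sep = "")
  invisible(x)
}

#' Tidy a fitted risk model
#'
#' For LR, per-code weights joined to the vocabulary; for the sequence
#' models, the per-epoch training history.
#'
#' @param x An `ehrisk_model`.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.ehrisk_model <- function(x, ...) {
  if (x$model_kind == "LR") {
    out <- tibble(index = seq_len(x$vocab_size), weight = x$params$w)
    if (!is.null(x$vocab)) {
      out <- left_join(out, x$vocab, by = "index") |>
        select("code", "code_type", "index", "weight")
    }
    return(out)
  }
  x$history
}

#' One-row summary of a fitted risk model
#'
#' @param x An `ehrisk_model`.
#' @param ... Unused.
#' @return A tibble: kind, epochs run, best epoch, best validation AUROC,
#'   parameter count, frozen threshold.
#' @exportS3Method generics::glance
glance.ehrisk_model <- function(x, ...) {
  tibble(
    model_kind = x$model_kind,
    stopped_epoch = x$stopped_epoch,
    best_epoch = x$best_epoch,
    best_val_auroc = max(x$history$val_auroc),
    n_parameters = sum(vapply(x$params, length, integer(1))),
    threshold = x$threshold
  )
}
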