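#' Fit a note classifier
#'
#' Trains a TextCNN or TextLSTM with the chosen numeric-embedding mode on
#' the training split, by Adam on the binary cross-entropy of the logit,
#' for the fixed number of epochs in the config (no early stopping; the
#' final-epoch weights are kept). The vocabulary is built from the
#' training split only. All randomness (weight init, epoch shuffling,
#' dropout) derives from `seed`, so two fits with the same inputs and seed
#' produce identical predictions.
#'
#' @param prepped [prep_corpus()] output for the whole corpus.
#' @param labels Integer/numeric 0-1 vector aligned with `prepped`.
#' @param train_idx,val_idx Index vectors into `prepped` for the training
#'   and validation splits (they must not overlap).
#' @param config A `textcnn_config` or `textlstm_config`.
#' @param mode Embedding mode, see [embedding_modes()].
#' @param seed Integer seed for this fit.
#' @param left,right Keyword context-window extents.
#' @param verbose Print per-epoch training loss.
#' @return Object of class `nr_model`: list with `weights`, `vocab`,
#'   `config`, `mode`, `left`, `right`, `history` (mean training loss per
#'   epoch), and `val_preds` (validation-set probabilities).
#' @export
fit_model <- function(prepped, labels, train_idx, val_idx = integer(0),
                      config = textcnn_config(), mode = "basic",
                      seed = 1L, left = 1L, right = 2L, verbose = FALSE) {
  mode <- match.arg(mode, embedding_modes())
  stopifnot(length(labels) == length(prepped),
            length(intersect(train_idx, val_idx)) == 0L,
            length(train_idx) > 0L)
  labels <- as.numeric(labels)
  set.seed(seed)
  vocab <- build_vocab(prepped[train_idx], mode)
  weights <- init_weights(vocab, config)
  encoded <- lapply(prepped, encode_for_fit, vocab = vocab,
                    max_len = config$max_len)
  adam <- NULL
  history <- numeric(config$epochs)
  n <- length(train_idx)
  bs <- config$batch_size
  for (epoch in seq_len(config$epochs)) {
    ord <- sample(train_idx)
    losses <- 0
    nb <- 0L
    for (start in seq(1L, n, by = bs)) {
      idx <- ord[start:min(start + bs - 1L, n)]
      batch <- make_batch(encoded, idx)
      emb <- embed_batch(batch, weights, config, left, right)
      if (config$arch == "textcnn") {
        fw <- cnn_forward_batch(batch, emb, weights, config, train = TRUE)
      } else {
        fw <- lstm_forward_batch(batch, emb, weights, config, train = TRUE)
      }
      y <- labels[idx]
      p <- sigmoid(fw$logits)
      eps <- 1e-12
      losses <- losses + mean(-(y * log(p + eps) + (1 - y) * log(1 - p + eps)))
      nb <- nb + 1L
      dlogits <- (p - y) / length(idx)
      gr <- if (config$arch == "textcnn") {
        cnn_backward_batch(batch, emb, fw, dlogits, weights, config)
      } else {
        lstm_backward_batch(batch, emb, fw, dlogits, weights, config)
      }
      if (is.null(adam)) adam <- adam_init(gr)
      st <- adam_step(weights, gr, adam, config$learning_rate)
      weights <- st$weights
      adam <- st$state
    }
    history[epoch] <- losses / nb
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f", epoch, history[epoch]))
    }
  }
  model <- structure(list(weights = weights, vocab = vocab, config = config,
                          mode = mode, left = left, right = right,
                          history = history, seed = seed),
                     class = "nr_model")
  model$val_preds <- if (length(val_idx) > 0L) {
    predict(model, prepped[val_idx])
  } else numeric(0)
  model
}

#' @export
print.nr_model <- function(x, ...) {
  cat(sprintf("<nr_model> %s / %s, vocab %d, %d epochs (final loss %.4f)\n",
              x$config$arch, x$mode, x$vocab$size,
              x$config$epochs, x$history[length(x$history)]))
  invisible(x)
}

#' Predict outcome probabilities
#'
#' Forward pass without dropout; sigmoid of the logit.
#'
#' @param object An `nr_model`.
#' @param prepped List of [prep_note()] results to score.
#' @param batch_size Scoring batch size.
#' @param ... Unused.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict.nr_model <- function(object, prepped, batch_size = 64L, ...) {
  encoded <- lapply(prepped, encode_for_fit, vocab = object$vocab,
                    max_len = object$config$max_len)
  n <- length(encoded)
  out <- numeric(n)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    batch <- make_batch(encoded, idx)
    emb <- embed_batch(batch, object$weights, object$config,
                       object$left, object$right)
    fw <- if (object$config$arch == "textcnn") {
      cnn_forward_batch(batch, emb, object$weights, object$config)
    } else {
      lstm_forward_batch(batch, emb, object$weights, object$config)
    }
    out[idx] <- sigmoid(fw$logits)
  }
  out
}

#' Forward records for attribution
#'
#' Runs the TextCNN forward pass (no dropout) on each note and keeps what
#' SHAP-N needs: the logit, the 176 pooled activations, and each filter's
#' argmax window position and size.
#'
#' @param model A TextCNN `nr_model`.
#' @param prepped List of [prep_note()] results.
#' @return List of forward records (see [textcnn_forward()]).
#' @export
forward_records <- function(model, prepped) {
  stopifnot(inherits(model, "nr_model"))
  if (model$config$arch != "textcnn") {
    stop("forward records (and SHAP-N) are defined for TextCNN only")
  }
  lapply(prepped, function(p) {
    ids <- encode_tokens(p, model$vocab, model$config$max_len)
    note <- embed_sequence(ids, p$mentions, model$mode, model$weights,
                           model$left, model$right)
    textcnn_forward(note, model$weights, model$config)
  })
}
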