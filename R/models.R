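#' TextCNN configuration
#'
#' Defaults reproduce the reference architecture: dimension-50 embeddings,
#' four convolutional filter layers of sizes (1, 2, 3, 5) with 44 kernels
#' each (176 filters total), valid (unpadded) convolution, a note-wide max
#' pool per filter, dropout 0.5 on the pooled vector feeding the final
#' linear layer, 100 epochs, batch size 64, learning rate 3.5e-4, and a
#' note length cutoff of 3000 tokens with zero padding.
#'
#' @param embed_dim,filter_sizes,n_kernels,dropout,epochs,batch_size,learning_rate,max_len
#'   Architecture and optimization settings, see Description.
#' @return Object of class `textcnn_config` (and `nr_config`).
#' @export
textcnn_config <- function(embed_dim = 50L, filter_sizes = c(1L, 2L, 3L, 5L),
                           n_kernels = 44L, dropout = 0.5, epochs = 100L,
                           batch_size = 64L, learning_rate = 3.5e-4,
                           max_len = 3000L) {
  structure(list(arch = "textcnn", embed_dim = embed_dim,
                 filter_sizes = filter_sizes, n_kernels = n_kernels,
                 n_filters = n_kernels * length(filter_sizes),
                 dropout = dropout, epochs = epochs, batch_size = batch_size,
                 learning_rate = learning_rate, max_len = max_len),
            class = c("textcnn_config", "nr_config"))
}

#' TextLSTM configuration
#'
#' Same skeleton as [textcnn_config()] with the convolutional layer replaced
#' by a bidirectional LSTM of hidden dimension 88 per direction (output
#' width 2 x 88 = 176, matching the TextCNN classification layer), a
#' temporal max pool over the output states, no dropout, and 50 epochs.
#'
#' @param embed_dim,hidden_dim,dropout,epochs,batch_size,learning_rate,max_len
#'   Architecture and optimization settings.
#' @return Object of class `textlstm_config` (and `nr_config`).
#' @export
textlstm_config <- function(embed_dim = 50L, hidden_dim = 88L, dropout = 0,
                            epochs = 50L, batch_size = 64L,
                            learning_rate = 3.5e-4, max_len = 3000L) {
  structure(list(arch = "textlstm", embed_dim = embed_dim,
                 hidden_dim = hidden_dim, n_filters = 2L * hidden_dim,
                 dropout = dropout, epochs = epochs, batch_size = batch_size,
                 learning_rate = learning_rate, max_len = max_len),
            class = c("textlstm_config", "nr_config"))
}

#' Read a model configuration from a YAML or JSON file
#'
#' The file holds an `arch` field (`"textcnn"` or `"textlstm"`) plus any
#' subset of the corresponding config fields; omitted fields keep their
#' defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `textcnn_config` or `textlstm_config`.
#' @export
read_model_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path)
  }
  arch <- vals$arch %||% "textcnn"
  vals$arch <- NULL
  maker <- if (arch == "textcnn") textcnn_config else textlstm_config
  allowed <- names(formals(maker))
  bad <- setdiff(names(vals), allowed)
  if (length(bad) > 0L) stop("unknown config fields: ",
                             paste(bad, collapse = ", "))
  do.call(maker, vals)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Initialize model weights
#'
#' Embedding table rows from a small uniform; the padding row (id 0) is
#' all-zero and never updated. Convolutional, recurrent and projection
#' weights use uniform fan-in scaling; offsets start at zero. ScaleNum and
#' attention parameters are created for the numeric-embedding modes only.
#'
#' @param vocab An `nr_vocab`.
#' @param config A `textcnn_config` or `textlstm_config`.
#' @return Object of class `nr_weights`.
#' @export
init_weights <- function(vocab, config) {
  D <- config$embed_dim
  V <- vocab$size
  emb <- matrix(stats::runif(V * D, -0.05, 0.05), V, D)
  emb[1L, ] <- 0                       # padding row
  w <- list(embed = emb, mode = vocab$mode)
  if (vocab$mode %in% c("scalenum", "attntonum")) {
    w$scalenum <- init_scalenum(embed_dim = D)
  }
  if (vocab$mode == "attntonum") w$attn <- init_attention(embed_dim = D)
  if (config$arch == "textcnn") {
    w$conv <- lapply(config$filter_sizes, function(k) {
      lim <- 1 / sqrt(D * k)
      list(W = matrix(stats::runif(D * k * config$n_kernels, -lim, lim),
                      D * k, config$n_kernels),
           b = numeric(config$n_kernels))
    })
    names(w$conv) <- paste0("k", config$filter_sizes)
  } else {
    H <- config$hidden_dim
    lim <- 1 / sqrt(H)
    dir <- function() list(
      Wx = matrix(stats::runif(D * 4L * H, -lim, lim), D, 4L * H),
      Wh = matrix(stats::runif(H * 4L * H, -lim, lim), H, 4L * H),
      b_ih = numeric(4L * H), b_hh = numeric(4L * H))
    w$lstm <- list(fwd = dir(), bwd = dir())
  }
  Fn <- config$n_filters
  w$fc_w <- stats::runif(Fn, -1 / sqrt(Fn), 1 / sqrt(Fn))
  w$fc_b <- 0
  structure(w, class = "nr_weights")
}

#' TextCNN forward pass
#'
#' Valid convolution of each filter over the embedded note, a note-wide max
#' pool per filter (rectified-linear activation applied to the
#' convolutional outputs), and a linear combination of the 176 pooled
#' activations into one logit: `logit = w0 + sum_f w_f a_f`. Windows lying
#' entirely in the padded tail all produce the filter offset, so they are
#' summarized by a single padding candidate; if it wins the max, the argmax
#' span resolves to padding tokens.
#'
#' @param note [embed_sequence()] output (list with `emb`, `mask`).
#' @param weights An `nr_weights` for a TextCNN.
#' @param config The `textcnn_config`.
#' @return A forward record: list with `logit`, `activations` (length 176),
#'   `argmax` (window start position per filter; `NA` when the padding
#'   candidate won), and `filter_size` (per filter).
#' @export
textcnn_forward <- function(note, weights, config) {
  emb <- note$emb
  L <- nrow(emb)
  n_real <- if (any(note$mask)) max(which(note$mask)) else 0L
  sizes <- config$filter_sizes
  nk <- config$n_kernels
  acts <- numeric(config$n_filters)
  argmax <- rep(NA_integer_, config$n_filters)
  fsize <- rep(sizes, each = nk)
  for (si in seq_along(sizes)) {
    k <- sizes[si]
    cv <- weights$conv[[si]]
    P_full <- L - k + 1L                     # nominal window count
    P <- min(n_real, P_full)                 # windows touching real tokens
    idx <- ((si - 1L) * nk + 1L):(si * nk)
    if (P >= 1L) {
      X <- unfold_windows(emb, k, P)
      s <- sweep(X %*% cv$W, 2L, cv$b, "+")  # P x nk conv outputs
      j <- max.col(t(s), ties.method = "first")
      best <- s[cbind(j, seq_len(nk))]
      am <- j
    } else {
      best <- rep(-Inf, nk)
      am <- rep(NA_integer_, nk)
    }
    if (P < P_full) {                        # pure-padding candidate
      pad_wins <- cv$b >= best
      best[pad_wins] <- cv$b[pad_wins]
      am[pad_wins] <- NA_integer_
    }
    a <- pmax(best, 0)
    acts[idx] <- a
    argmax[idx] <- am
  }
  logit <- weights$fc_b + sum(weights$fc_w * acts)
  list(logit = logit, activations = acts, argmax = argmax,
       filter_size = fsize)
}

# Stack the k-token windows starting at 1..P into a P x (D*k) matrix.
unfold_windows <- function(emb, k, P) {
  D <- ncol(emb)
  L <- nrow(emb)
  if (k == 1L) return(emb[seq_len(P), , drop = FALSE])
  out <- matrix(0, P, D * k)
  for (j in seq_len(k)) {
    rows <- seq.int(j, length.out = P)
    keep <- rows <= L
    out[keep, ((j - 1L) * D + 1L):(j * D)] <- emb[rows[keep], , drop = FALSE]
  }
  out
}

# One LSTM direction over a T x D input; returns T x H hidden states.
# Gate order i, f, g, o; two offset vectors per gate bank.
lstm_direction <- function(x, p, H) {
  T_ <- nrow(x)
  hs <- matrix(0, T_, H)
  h <- numeric(H); c <- numeric(H)
  bias <- p$b_ih + p$b_hh
  pre_x <- sweep(x %*% p$Wx, 2L, bias, "+")
  for (t in seq_len(T_)) {
    z <- pre_x[t, ] + drop(h %*% p$Wh)
    i <- sigmoid(z[seq_len(H)])
    f <- sigmoid(z[H + seq_len(H)])
    g <- tanh(z[2L * H + seq_len(H)])
    o <- sigmoid(z[3L * H + seq_len(H)])
    c <- f * c + i * g
    h <- o * tanh(c)
    hs[t, ] <- h
  }
  hs
}

#' TextLSTM forward pass
#'
#' Bidirectional LSTM over the real (unpadded) tokens, concatenating the
#' two directions into 176-wide output states, a temporal max pool, and a
#' linear layer to one logit. Padded positions are masked out of both the
#' recurrence and the pool, so the logit is invariant to the padded tail.
#'
#' @param note [embed_sequence()] output.
#' @param weights An `nr_weights` for a TextLSTM.
#' @param config The `textlstm_config`.
#' @return List with `logit` and `pooled` (the 176-vector after the max
#'   pool).
#' @export
textlstm_forward <- function(note, weights, config) {
  H <- config$hidden_dim
  n_real <- if (any(note$mask)) max(which(note$mask)) else 0L
  if (n_real == 0L) {
    pooled <- numeric(2L * H)
  } else {
    x <- note$emb[seq_len(n_real), , drop = FALSE]
    hf <- lstm_direction(x, weights$lstm$fwd, H)
    hb <- lstm_direction(x[rev(seq_len(n_real)), , drop = FALSE],
                         weights$lstm$bwd, H)
    states <- cbind(hf, hb[rev(seq_len(n_real)), , drop = FALSE])
    pooled <- apply(states, 2L, max)
  }
  logit <- weights$fc_b + sum(weights$fc_w * pooled)
  list(logit = logit, pooled = pooled)
}

#' Itemized learnable-parameter counts
#'
#' Closed-form accounting of every learnable scalar, by component: the
#' embedding table (`vocab_size` x embed dim), the ScaleNum number
#' embedding (K slope + offset vectors), the attention block (four
#' projections with offsets), and the post-embedding layers
#' (convolutional or recurrent plus the classification layer).
#'
#' @param config A `textcnn_config` or `textlstm_config`.
#' @param vocab_size Embedding-table row count (including the padding row).
#' @param mode Embedding mode, see [embedding_modes()].
#' @param n_transforms,heads ScaleNum transform count and attention heads.
#' @return Object of class `parameter_breakdown`: list with `embed`,
#'   `number_embedding`, `attention`, `post_embed`, `total`.
#' @examples
#' count_parameters(textcnn_config(), 9408, mode = "attntonum")
#' @export
count_parameters <- function(config, vocab_size, mode = "basic",
                             n_transforms = 5L, heads = 5L) {
  mode <- match.arg(mode, embedding_modes())
  D <- config$embed_dim
  embed <- vocab_size * D
  number_embedding <-
    if (mode %in% c("scalenum", "attntonum")) n_transforms * 2L * D else 0L
  attention <- if (mode == "attntonum") 4L * (D * D + D) else 0L
  post_embed <- if (config$arch == "textcnn") {
    sum(D * config$filter_sizes * config$n_kernels) +
      length(config$filter_sizes) * config$n_kernels +
      (config$n_filters + 1L)
  } else {
    H <- config$hidden_dim
    2L * (4L * H * (D + H) + 2L * 4L * H) + (config$n_filters + 1L)
  }
  structure(list(embed = embed, number_embedding = number_embedding,
                 attention = attention, post_embed = post_embed,
                 total = embed + number_embedding + attention + post_embed),
            class = "parameter_breakdown")
}

#' @export
print.parameter_breakdown <- function(x, ...) {
  cat(sprintf(
    "embed %s | number embedding %s | attention %s | post-embed %s | total %s\n",
    format(x$embed, big.mark = ","), format(x$number_embedding, big.mark = ","),
    format(x$attention, big.mark = ","), format(x$post_embed, big.mark = ","),
    format(x$total, big.mark = ",")))
  invisible(x)
}
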