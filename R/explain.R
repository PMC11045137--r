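#' Per-filter SHAP decomposition for TextCNN
#'
#' Because each convolutional filter contributes exactly one max-pooled
#' activation to the logit, the logit decomposes additively over filters:
#' `logit_s = w0 + sum_f w_f a_{s,f}`. Centering each filter's activation
#' on its dataset mean gives exact Shapley values for this additive game:
#' `phi_{f,s} = w_f (a_{s,f} - mu_f)` with base value
#' `phi0 = w0 + sum_f w_f mu_f`, so `phi0 + sum_f phi_{f,s} = logit_s`
#' exactly for every sample.
#'
#' @param model A TextCNN `nr_model` (the additive max-pool structure is
#'   required; LSTM models are refused).
#' @param records List of forward records from [forward_records()] over
#'   the dataset being explained (holdout or validation split).
#' @return Object of class `shap_decomposition`: list with `phi0`, `mu`
#'   (per-filter means), `w` (filter coefficients), and per-sample list
#'   `samples` of lists with `phi` (length 176), `logit`, `argmax`,
#'   `filter_size`.
#' @export
shap_filters <- function(model, records) {
  stopifnot(inherits(model, "nr_model"))
  if (model$config$arch != "textcnn") {
    stop("SHAP-N requires the additive max-pool structure of TextCNN")
  }
  acts <- do.call(rbind, lapply(records, function(r) r$activations))
  mu <- colMeans(acts)
  w <- model$weights$fc_w
  phi0 <- model$weights$fc_b + sum(w * mu)
  samples <- lapply(records, function(r) {
    list(phi = w * (r$activations - mu), logit = r$logit,
         argmax = r$argmax, filter_size = r$filter_size)
  })
  structure(list(phi0 = phi0, mu = mu, w = w, samples = samples),
            class = "shap_decomposition")
}

#' Aggregate per-filter SHAP values to ngram resolution
#'
#' Each filter's argmax window is a token span (length = filter size).
#' Spans that are identical pool their SHAP values, and a span contained
#' in a longer passing span is pooled into that span's ngram (sub-ngrams
#' of a passing ngram pass other max pools and would otherwise fragment
#' the attribution). Each filter is assigned to exactly one ngram --
#' containment ties go to the longer span, then the leftmost -- so the
#' per-sample SHAP-N values conserve the logit:
#' `phi0 + sum_n phi_{n,s} = logit_s`.
#'
#' Filters whose max came from a pure-padding window carry their SHAP
#' value on the empty ngram `"<pad>"`.
#'
#' @param sample One element of a `shap_decomposition`'s `samples`.
#' @param tokens The note's transformed token vector (the stream the
#'   model saw, e.g. `transform_tokens(prepped, mode)`).
#' @param merge_overlaps Also set-union merely overlapping (not nested)
#'   spans into longer features. Off by default: overlap merging smooths
#'   long runs into hard-to-read features, so resolution is left at the
#'   ngram level.
#' @return data.frame with columns `ngram`, `start`, `size`, `phi`,
#'   `n_filters`.
#' @export
aggregate_ngrams <- function(sample, tokens, merge_overlaps = FALSE) {
  phi <- sample$phi
  start <- sample$argmax
  size <- sample$filter_size
  pad <- is.na(start)
  key_start <- ifelse(pad, 0L, start)
  key_end <- ifelse(pad, -1L, start + size - 1L)
  # assign every span to a maximal covering span
  n <- length(phi)
  ord <- order(-(key_end - key_start), key_start)     # longer, then leftmost
  owner <- rep(NA_integer_, n)
  maximal <- integer(0)
  for (f in ord) {
    if (pad[f]) next
    hit <- NA_integer_
    for (m in maximal) {
      if (key_start[m] <= key_start[f] && key_end[f] <= key_end[m]) {
        hit <- m
        break
      }
    }
    if (is.na(hit)) {
      maximal <- c(maximal, f)
      owner[f] <- f
    } else {
      owner[f] <- hit
    }
  }
  if (merge_overlaps && length(maximal) > 1L) {
    # set-union chains of overlapping maximal spans
    ms <- maximal[order(key_start[maximal])]
    group_of <- owner
    cur <- ms[1L]
    for (m in ms[-1L]) {
      if (key_start[m] <= key_end[cur]) {
        key_end[cur] <- max(key_end[cur], key_end[m])
        group_of[owner == m] <- cur
      } else {
        cur <- m
      }
    }
    owner <- group_of
  }
  groups <- split(seq_len(n)[!pad], owner[!pad])
  rows <- lapply(groups, function(fs) {
    o <- owner[fs[1L]]
    s <- key_start[o]; e <- key_end[o]
    ng <- paste(tokens[s:min(e, length(tokens))], collapse = " ")
    data.frame(ngram = ng, start = s, size = e - s + 1L,
               phi = sum(phi[fs]), n_filters = length(fs),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (any(pad)) {
    out <- rbind(out, data.frame(ngram = "<pad>", start = NA_integer_,
                                 size = 0L, phi = sum(phi[pad]),
                                 n_filters = sum(pad)))
  }
  if (is.null(out)) {
    out <- data.frame(ngram = character(0), start = integer(0),
                      size = integer(0), phi = numeric(0),
                      n_filters = integer(0))
  }
  out
}

#' Dataset-mean SHAP-N table
#'
#' Averages each ngram's per-sample SHAP-N value over **all** samples
#' (samples where the ngram does not pass any max pool contribute 0), and
#' ranks ngrams by the mean. The support count reports in how many
#' samples the ngram actually passed.
#'
#' @param ngram_tables List of [aggregate_ngrams()] outputs, one per
#'   sample of the dataset.
#' @return data.frame with columns `ngram`, `phi` (dataset mean),
#'   `support`, sorted by decreasing `phi`.
#' @export
mean_shapn <- function(ngram_tables) {
  S <- length(ngram_tables)
  all_tab <- do.call(rbind, ngram_tables)
  agg <- stats::aggregate(all_tab$phi, by = list(ngram = all_tab$ngram), sum)
  sup <- stats::aggregate(rep(1L, nrow(all_tab)),
                          by = list(ngram = all_tab$ngram), sum)
  out <- data.frame(ngram = agg$ngram, phi = agg$x / S, support = sup$x,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$phi), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Correlation between two number embeddings
#'
#' Embeds two probe phrases of the form `"[BUN|creatinine] [value]
#' ([L|H])"` with a trained model and returns the Pearson correlation of
#' the two number-token embedding vectors at the requested stage of the
#' pipeline: `rooc` (table lookup), `scalenum` (magnitude scaling), or
#' `attntonum` (after context attention).
#'
#' @param phrase1,phrase2 Probe phrases, each containing one in-context
#'   number.
#' @param model A trained `nr_model` (mode `scalenum` or `attntonum` for
#'   the corresponding stages).
#' @param stage One of `"rooc"`, `"scalenum"`, `"attntonum"`.
#' @return Pearson correlation coefficient.
#' @export
embedding_correlation <- function(phrase1, phrase2, model,
                                  stage = c("attntonum", "scalenum",
                                            "rooc")) {
  stage <- match.arg(stage)
  v1 <- number_embedding(phrase1, model, stage)
  v2 <- number_embedding(phrase2, model, stage)
  stats::cor(v1, v2)
}

number_embedding <- function(phrase, model, stage) {
  p <- prep_note(phrase)
  mn <- p$mentions[p$mentions$in_context, , drop = FALSE]
  if (nrow(mn) == 0L) stop("phrase has no in-context parseable number: ",
                           phrase)
  mn <- mn[1L, , drop = FALSE]
  if (stage == "rooc") {
    ids <- encode_tokens(p, model$vocab, max_len = length(p$tokens))
    return(model$weights$embed[ids[mn$position] + 1L, ])
  }
  if (stage == "scalenum") {
    return(scalenum_embed(mn$value, model$weights$scalenum))
  }
  ids <- encode_tokens(p, model$vocab, max_len = length(p$tokens))
  note <- embed_sequence(ids, p$mentions, "attntonum", model$weights,
                         model$left, model$right)
  note$emb[mn$position, ]
}

#' Attention weights over a probe phrase's context window
#'
#' Extracts the per-head attention weights a trained AttnToNum model
#' assigns over the context-window tokens of the phrase's in-context
#' number. Rows (heads) sum to 1.
#'
#' @param phrase Probe phrase containing one in-context number.
#' @param model A trained `nr_model` with mode `"attntonum"`.
#' @return Matrix heads x window, with window tokens as column names.
#' @export
attention_weights <- function(phrase, model) {
  stopifnot(model$mode == "attntonum")
  p <- prep_note(phrase)
  mn <- p$mentions[p$mentions$in_context, , drop = FALSE]
  if (nrow(mn) == 0L) stop("phrase has no in-context number")
  mn <- mn[1L, , drop = FALSE]
  ids <- encode_tokens(p, model$vocab, max_len = length(p$tokens))
  note <- embed_sequence(ids, p$mentions, "scalenum", model$weights,
                         model$left, model$right)
  win <- context_window(mn$keyword_position, model$left, model$right,
                        length(p$tokens))
  res <- attn_to_num(mn$value, note$emb[win, , drop = FALSE],
                     model$weights$scalenum, model$weights$attn,
                     return_weights = TRUE)
  W <- res$weights
  colnames(W) <- p$tokens[win]
  rownames(W) <- paste0("head", seq_len(nrow(W)))
  W
}
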