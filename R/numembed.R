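#' @keywords internal
sigmoid <- function(z) 1 / (1 + exp(-z))

#' Single sigmoid-linear-log scaling transform
#'
#' The building block of the ScaleNum embedding. The value is clamped to
#' `[lo, hi]` (defaults 1 and 1000 -- lab values of interest always fall
#' inside, so the clamp costs no information while guaranteeing a finite
#' log), log-transformed, passed through an elementwise affine map, and
#' squashed: `g(x) = sigmoid(a * log(clamp(x, lo, hi)) + b)`. Equivalently
#' `g(x) = x^a e^b / (x^a e^b + 1)` on the clamped value.
#'
#' @param x Strictly positive scalar.
#' @param a,b Numeric vectors of the embedding dimension (slope and offset
#'   of the affine map, per dimension).
#' @param lo,hi Clamp bounds, `0 < lo < hi`.
#' @return Numeric vector like `a`, every component strictly in (0, 1).
#' @examples
#' g_single(24, rep(0, 50), rep(0, 50))  # all 0.5
#' @export
g_single <- function(x, a, b, lo = 1, hi = 1000) {
  stopifnot(length(x) == 1L, x > 0, length(a) == length(b), lo > 0, lo < hi)
  sigmoid(a * log(min(max(x, lo), hi)) + b)
}

#' Initialize ScaleNum parameters
#'
#' `n_transforms` independent `g(x)` transforms, each with slope and offset
#' vectors of the embedding dimension, drawn from a small-variance normal so
#' the initial embedding is near-constant (0.5 per transform) and training
#' shapes the scaling.
#'
#' @param embed_dim Embedding dimension (default 50).
#' @param n_transforms Number of summed transforms (default 5).
#' @param sd Standard deviation of the normal initializer.
#' @param lo,hi Clamp bounds.
#' @return Object of class `scalenum_params`: list with matrices `a`, `b`
#'   (`n_transforms` x `embed_dim`) and scalars `lo`, `hi`.
#' @export
init_scalenum <- function(embed_dim = 50L, n_transforms = 5L, sd = 0.1,
                          lo = 1, hi = 1000) {
  structure(list(
    a = matrix(stats::rnorm(n_transforms * embed_dim, sd = sd),
               n_transforms, embed_dim),
    b = matrix(stats::rnorm(n_transforms * embed_dim, sd = sd),
               n_transforms, embed_dim),
    lo = lo, hi = hi), class = "scalenum_params")
}

#' ScaleNum embedding of a positive number
#'
#' Sum of the `K` learned `g(x)` transforms. Numbers of similar magnitude
#' land close in embedding space regardless of surface form, which is what
#' lets the downstream classifier generalize across unseen lab values.
#'
#' @param x Strictly positive scalar.
#' @param params A `scalenum_params` object, see [init_scalenum()].
#' @return Numeric vector of the embedding dimension; every component lies
#'   strictly in `(0, K)`.
#' @export
scalenum_embed <- function(x, params) {
  stopifnot(inherits(params, "scalenum_params"), length(x) == 1L, x > 0)
  z <- log(min(max(x, params$lo), params$hi))
  colSums(sigmoid(params$a * z + params$b))
}

#' Initialize context-attention parameters
#'
#' Query/key/value/output projections of a multi-head attention block over
#' the keyword context window. Projections use uniform fan-in scaling,
#' offsets start at zero.
#'
#' @param embed_dim Model dimension (default 50); must be divisible by
#'   `heads`.
#' @param heads Number of attention heads (default 5; head dim 10).
#' @return Object of class `attn_params`: matrices `Wq`, `Wk`, `Wv`, `Wo`
#'   (`embed_dim` x `embed_dim`), offsets `bq`, `bk`, `bv`, `bo`, plus
#'   `heads` and `d_h`.
#' @export
init_attention <- function(embed_dim = 50L, heads = 5L) {
  stopifnot(embed_dim %% heads == 0L)
  lim <- 1 / sqrt(embed_dim)
  pm <- function() matrix(stats::runif(embed_dim^2, -lim, lim),
                          embed_dim, embed_dim)
  structure(list(Wq = pm(), Wk = pm(), Wv = pm(), Wo = pm(),
                 bq = numeric(embed_dim), bk = numeric(embed_dim),
                 bv = numeric(embed_dim), bo = numeric(embed_dim),
                 heads = heads, d_h = embed_dim %/% heads),
            class = "attn_params")
}

# Multi-head attention with a single query over a small context window.
# g: query vector (the number's ScaleNum embedding), C: m x D matrix of
# window-token embeddings (the number's own slot holds g). Returns the
# refined embedding plus everything backprop needs.
attn_forward <- function(g, C, attn) {
  H <- attn$heads; dh <- attn$d_h; D <- length(g)
  q <- drop(g %*% attn$Wq) + attn$bq
  K <- sweep(C %*% attn$Wk, 2L, attn$bk, "+")
  V <- sweep(C %*% attn$Wv, 2L, attn$bv, "+")
  m <- nrow(C)
  W <- matrix(0, H, m)           # attention weights, row-stochastic
  o <- numeric(D)                # concatenated head outputs
  for (h in seq_len(H)) {
    idx <- ((h - 1L) * dh + 1L):(h * dh)
    s <- drop(K[, idx, drop = FALSE] %*% q[idx]) / sqrt(dh)
    s <- s - max(s)
    w <- exp(s); w <- w / sum(w)
    W[h, ] <- w
    o[idx] <- drop(w %*% V[, idx, drop = FALSE])
  }
  e <- drop(o %*% attn$Wo) + attn$bo
  list(e = e, weights = W, q = q, K = K, V = V, o = o)
}

#' Attention-refined number embedding (AttnToNum)
#'
#' Refines a ScaleNum embedding with multi-head attention over the tokens
#' of the keyword context window, so the refined embedding reflects both
#' the number's magnitude and what kind of lab it is. The query is the
#' number's ScaleNum embedding; keys and values are the window-token
#' embeddings (the number's own slot holding its ScaleNum embedding).
#' The attention output replaces the ScaleNum embedding.
#'
#' @param x Strictly positive scalar (the mentioned value).
#' @param context_embeds Matrix (window size x embed dim) of the context
#'   window's token embeddings; may have zero rows.
#' @param scalenum A `scalenum_params` object.
#' @param attn An `attn_params` object.
#' @param return_weights If `TRUE`, also return the head-by-window matrix
#'   of attention weights.
#' @return The refined embedding vector; with `return_weights = TRUE`, a
#'   list with `embedding` and `weights` (rows sum to 1). An empty context
#'   window returns the ScaleNum embedding unchanged.
#' @export
attn_to_num <- function(x, context_embeds, scalenum, attn,
                        return_weights = FALSE) {
  g <- scalenum_embed(x, scalenum)
  if (is.null(context_embeds) || nrow(context_embeds) == 0L) {
    if (return_weights) {
      return(list(embedding = g, weights = matrix(0, attn$heads, 0L)))
    }
    return(g)
  }
  fw <- attn_forward(g, context_embeds, attn)
  if (return_weights) list(embedding = fw$e, weights = fw$weights) else fw$e
}

#' Embed an encoded note
#'
#' Produces the `max_len` x `embed_dim` embedding matrix a classifier
#' consumes. All modes look ordinary tokens up in the embedding table
#' (padding id 0 is an all-zero row). In `scalenum` mode, each in-context
#' number's row is replaced by its ScaleNum embedding; `attntonum` further
#' refines those rows by context attention. Mentions beyond the encoded
#' length are ignored.
#'
#' @param ids Integer id vector from [encode_tokens()].
#' @param mentions Mention table for the same note.
#' @param mode Embedding mode, see [embedding_modes()].
#' @param weights Model weights holding `embed` (table with `vocab$size`
#'   rows, row 1 = padding), and for the numeric modes `scalenum` /
#'   `attn`.
#' @param left,right Context-window extents used for `attntonum`.
#' @return List with `emb` (matrix `length(ids)` x embed dim; padding rows
#'   all zero) and `mask` (logical vector of real-token positions).
#' @export
embed_sequence <- function(ids, mentions, mode, weights,
                           left = 1L, right = 2L) {
  mode <- match.arg(mode, embedding_modes())
  L <- length(ids)
  emb <- weights$embed[ids + 1L, , drop = FALSE]
  mask <- ids != 0L
  if (mode %in% c("scalenum", "attntonum") && nrow(mentions) > 0L) {
    mn <- mentions[mentions$in_context & mentions$position <= L, ,
                   drop = FALSE]
    if (nrow(mn) > 0L) {
      for (i in seq_len(nrow(mn))) {
        emb[mn$position[i], ] <- scalenum_embed(mn$value[i],
                                                weights$scalenum)
      }
      if (mode == "attntonum") {
        n_real <- if (any(mask)) max(which(mask)) else 0L
        refined <- vector("list", nrow(mn))
        for (i in seq_len(nrow(mn))) {
          win <- context_window(mn$keyword_position[i], left, right, n_real)
          refined[[i]] <- attn_to_num(
            mn$value[i], emb[win, , drop = FALSE],
            weights$scalenum, weights$attn)
        }
        for (i in seq_len(nrow(mn))) emb[mn$position[i], ] <- refined[[i]]
      }
    }
  }
  emb[!mask, ] <- 0
  list(emb = emb, mask = mask)
}

# Window of token positions attended over for a mention governed by the
# keyword at kp; clipped to the real tokens.
context_window <- function(kp, left, right, n_real) {
  if (is.na(kp)) return(integer(0))
  w <- (kp - left):(kp + right)
  w[w >= 1L & w <= n_real]
}
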