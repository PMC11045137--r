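# Batched training engine for TextCNN / TextLSTM.
#
# Notes are embedded per batch into a flat (B*L) x D matrix whose row for
# note b, position l is b + (l-1)*B; window unfolding then reduces the
# convolution to one GEMM per filter size. Backward only routes gradient
# through each filter's argmax window (the max pool), so the backward cost
# is proportional to the number of filters, not positions.

# ---- batch assembly ---------------------------------------------------

# Encode one prepped note for the engine: ids trimmed to the true encoded
# length, and the in-context mentions that fall inside it.
encode_for_fit <- function(prepped, vocab, max_len) {
  ids_full <- encode_tokens(prepped, vocab, max_len)
  n_real <- length(prepped$tokens)
  n <- as.integer(min(n_real, max_len))
  mn <- prepped$mentions
  mn <- mn[mn$in_context & mn$position <= n, , drop = FALSE]
  list(ids = ids_full[seq_len(max(n, 1L))], n = n, mentions = mn)
}

make_batch <- function(encoded, idx) {
  B <- length(idx)
  lens <- vapply(encoded[idx], function(e) e$n, integer(1))
  Lb <- max(lens, 1L)
  ids <- matrix(0L, B, Lb)
  mb <- vector("list", B)
  for (i in seq_len(B)) {
    e <- encoded[[idx[i]]]
    if (e$n > 0L) ids[i, seq_len(e$n)] <- e$ids[seq_len(e$n)]
    mn <- e$mentions
    if (nrow(mn) > 0L) {
      mn$b <- i
      mb[[i]] <- mn
    }
  }
  mentions <- do.call(rbind, mb)
  if (is.null(mentions)) {
    mentions <- data.frame(position = integer(0), value = numeric(0),
                           keyword = character(0),
                           keyword_position = integer(0),
                           in_context = logical(0), b = integer(0))
  }
  list(ids = ids, lens = lens, B = B, Lb = Lb, mentions = mentions)
}

# ---- embedding forward ------------------------------------------------

# Returns the flat (B*Lb) x D post-override embedding matrix plus caches
# for the numeric-embedding backward passes.
embed_batch <- function(batch, weights, config, left = 1L, right = 2L) {
  B <- batch$B; Lb <- batch$Lb
  flat_ids <- as.vector(batch$ids)          # (b, l) -> b + (l-1)*B
  E <- weights$embed[flat_ids + 1L, , drop = FALSE]
  mode <- weights$mode
  mn <- batch$mentions
  sn_cache <- NULL; attn_cache <- NULL
  if (mode %in% c("scalenum", "attntonum") && nrow(mn) > 0L) {
    rows <- mn$b + (mn$position - 1L) * B
    sn <- scalenum_batch(mn$value, weights$scalenum)
    E[rows, ] <- sn$G
    sn_cache <- list(rows = rows, z = sn$z, S = sn$S)
    if (mode == "attntonum") {
      caches <- vector("list", nrow(mn))
      refined <- matrix(0, nrow(mn), ncol(E))
      for (i in seq_len(nrow(mn))) {
        win <- context_window(mn$keyword_position[i], left, right,
                              batch$lens[mn$b[i]])
        if (length(win) == 0L) {
          refined[i, ] <- E[rows[i], ]
          caches[[i]] <- list(empty = TRUE)
        } else {
          wrows <- mn$b[i] + (win - 1L) * B
          fw <- attn_forward(E[rows[i], ], E[wrows, , drop = FALSE],
                             weights$attn)
          refined[i, ] <- fw$e
          caches[[i]] <- list(empty = FALSE, fw = fw, wrows = wrows,
                              C = E[wrows, , drop = FALSE],
                              g = E[rows[i], ])
        }
      }
      E[rows, ] <- refined
      attn_cache <- caches
    }
  }
  list(E = E, flat_ids = flat_ids, sn = sn_cache, attn = attn_cache)
}

# Vectorized ScaleNum over a vector of values: G is n x D, S the per-
# transform sigmoids (n x K x D) kept for backward.
scalenum_batch <- function(values, params) {
  z <- log(pmin(pmax(values, params$lo), params$hi))
  K <- nrow(params$a); D <- ncol(params$a); n <- length(values)
  S <- array(0, c(n, K, D))
  G <- matrix(0, n, D)
  for (k in seq_len(K)) {
    sk <- sigmoid(outer(z, params$a[k, ]) +
                    matrix(params$b[k, ], n, D, byrow = TRUE))
    S[, k, ] <- sk
    G <- G + sk
  }
  list(G = G, z = z, S = S)
}

# ---- TextCNN ----------------------------------------------------------

cnn_forward_batch <- function(batch, emb, weights, config, train = FALSE) {
  B <- batch$B; Lb <- batch$Lb
  D <- config$embed_dim; nk <- config$n_kernels
  sizes <- config$filter_sizes
  E <- emb$E
  pooled <- matrix(0, B, config$n_filters)
  argmax <- matrix(NA_integer_, B, config$n_filters)
  Xs <- vector("list", length(sizes))
  for (si in seq_along(sizes)) {
    k <- sizes[si]
    cv <- weights$conv[[si]]
    P <- max(Lb - k + 1L, 0L)
    cols <- ((si - 1L) * nk + 1L):(si * nk)
    if (P >= 1L) {
      X <- matrix(0, B * P, D * k)
      for (j in seq_len(k)) {
        X[, ((j - 1L) * D + 1L):(j * D)] <-
          E[((j - 1L) * B + 1L):((P + j - 1L) * B), ]
      }
      S <- sweep(X %*% cv$W, 2L, cv$b, "+")   # (B*P) x nk
      A <- array(S, c(B, P, nk))
      M <- matrix(aperm(A, c(2L, 1L, 3L)), P, B * nk)
      jj <- max.col(t(M), ties.method = "first")
      best <- M[cbind(jj, seq_len(B * nk))]
      Xs[[si]] <- X
    } else {
      jj <- rep(NA_integer_, B * nk)
      best <- rep(-Inf, B * nk)
      Xs[si] <- list(NULL)
    }
    # pure-padding windows exist whenever the nominal length cutoff leaves
    # room beyond this batch's real tokens; they all score the offset
    pad_ok <- rep(batch$lens < config$max_len - k + 1L, times = nk)
    bias_rep <- rep(cv$b, each = B)
    take_pad <- pad_ok & (bias_rep >= best)
    best[take_pad] <- bias_rep[take_pad]
    jj[take_pad] <- NA_integer_
    pooled[, cols] <- matrix(pmax(best, 0), B, nk)
    argmax[, cols] <- matrix(jj, B, nk)
  }
  drop_mask <- NULL
  pd <- pooled
  if (train && config$dropout > 0) {
    keep <- 1 - config$dropout
    drop_mask <- matrix(stats::rbinom(B * config$n_filters, 1L, keep) / keep,
                        B, config$n_filters)
    pd <- pooled * drop_mask
  }
  logits <- drop(pd %*% weights$fc_w) + weights$fc_b
  list(logits = logits, pooled = pooled, pooled_dropped = pd,
       drop_mask = drop_mask, argmax = argmax, Xs = Xs)
}

cnn_backward_batch <- function(batch, emb, fw, dlogits, weights, config) {
  B <- batch$B; D <- config$embed_dim; nk <- config$n_kernels
  sizes <- config$filter_sizes
  gr <- new_grads(weights, config)
  gr$fc_b <- sum(dlogits)
  gr$fc_w <- drop(crossprod(fw$pooled_dropped, dlogits))
  dpool <- outer(dlogits, weights$fc_w)
  if (!is.null(fw$drop_mask)) dpool <- dpool * fw$drop_mask
  dpool[fw$pooled <= 0] <- 0                 # ReLU gate
  dE <- matrix(0, nrow(emb$E), D)
  for (si in seq_along(sizes)) {
    k <- sizes[si]
    cols <- ((si - 1L) * nk + 1L):(si * nk)
    da <- dpool[, cols, drop = FALSE]        # B x nk
    am <- fw$argmax[, cols, drop = FALSE]
    live <- which(da != 0)                   # linear over B x nk
    if (length(live) == 0L) next
    bidx <- ((live - 1L) %% B) + 1L
    fidx <- ((live - 1L) %/% B) + 1L
    dav <- da[live]
    pos <- am[live]
    fb <- sort(unique(fidx))
    bvec <- numeric(nk); bvec[fb] <- rowsum(dav, fidx)[, 1L]
    gr$conv[[si]]$b <- bvec
    real <- !is.na(pos)                      # padding winners touch b only
    if (any(real)) {
      X <- fw$Xs[[si]]
      sel <- bidx[real] + (pos[real] - 1L) * B
      R <- X[sel, , drop = FALSE] * dav[real]
      agg <- rowsum(R, fidx[real])
      fset <- as.integer(rownames(agg))
      dW <- matrix(0, D * k, nk)
      dW[, fset] <- t(agg)
      gr$conv[[si]]$W <- dW
      # input gradient: scatter da * W[, f] into the argmax windows
      Mw <- t(weights$conv[[si]]$W)[fidx[real], , drop = FALSE] * dav[real]
      dXagg <- rowsum(Mw, sel)
      urows <- as.integer(rownames(dXagg))
      for (j in seq_len(k)) {
        dE[urows + (j - 1L) * B, ] <-
          dE[urows + (j - 1L) * B, , drop = FALSE] +
          dXagg[, ((j - 1L) * D + 1L):(j * D), drop = FALSE]
      }
    }
  }
  backprop_embedding(batch, emb, dE, gr, weights, config)
}

# ---- shared embedding backward ---------------------------------------

# dE holds gradient w.r.t. the post-override embedding matrix; route it
# through attention and ScaleNum into the parameter gradients, and the
# remainder into the embedding table.
backprop_embedding <- function(batch, emb, dE, gr, weights, config) {
  B <- batch$B
  mode <- weights$mode
  mn <- batch$mentions
  if (mode %in% c("scalenum", "attntonum") && nrow(mn) > 0L) {
    rows <- emb$sn$rows
    dG <- matrix(0, nrow(mn), config$embed_dim)
    if (mode == "attntonum") {
      de_list <- dE[rows, , drop = FALSE]
      dE[rows, ] <- 0
      row_of_mention <- structure(seq_along(rows), names = rows)
      for (i in seq_len(nrow(mn))) {
        cache <- emb$attn[[i]]
        if (isTRUE(cache$empty)) {
          dG[i, ] <- dG[i, ] + de_list[i, ]
          next
        }
        bk <- attn_backward(de_list[i, ], cache, weights$attn)
        gr$attn <- tree_add(gr$attn, bk$grads)
        dG[i, ] <- dG[i, ] + bk$dg
        for (w in seq_along(cache$wrows)) {
          r <- cache$wrows[w]
          j <- row_of_mention[as.character(r)]
          if (!is.na(j)) {
            dG[j, ] <- dG[j, ] + bk$dC[w, ]   # window slot held that g
          } else {
            dE[r, ] <- dE[r, ] + bk$dC[w, ]
          }
        }
      }
    } else {
      dG <- dE[rows, , drop = FALSE]
      dE[rows, ] <- 0
    }
    sg <- scalenum_backward(dG, emb$sn, weights$scalenum)
    gr$scalenum$a <- gr$scalenum$a + sg$da
    gr$scalenum$b <- gr$scalenum$b + sg$db
  }
  live <- which(rowSums(dE != 0) > 0L)
  if (length(live) > 0L) {
    ids <- emb$flat_ids[live]
    agg <- rowsum(dE[live, , drop = FALSE], ids)
    uid <- as.integer(rownames(agg))
    keep <- uid != 0L                        # padding row stays frozen
    gr$embed[uid[keep] + 1L, ] <- gr$embed[uid[keep] + 1L, , drop = FALSE] +
      agg[keep, , drop = FALSE]
  }
  gr
}

scalenum_backward <- function(dG, sn_cache, params) {
  K <- nrow(params$a)
  da <- matrix(0, K, ncol(params$a))
  db <- matrix(0, K, ncol(params$b))
  z <- sn_cache$z
  for (k in seq_len(K)) {
    sk <- sn_cache$S[, k, , drop = FALSE]
    dim(sk) <- dim(dG)
    dpre <- dG * sk * (1 - sk)
    da[k, ] <- colSums(dpre * z)
    db[k, ] <- colSums(dpre)
  }
  list(da = da, db = db)
}

# Backward through single-query multi-head attention. de: gradient of the
# refined embedding. Returns parameter grads plus dg (query + self paths
# are NOT included here; dg covers only the query projection path) and dC.
attn_backward <- function(de, cache, attn) {
  fw <- cache$fw
  H <- attn$heads; dh <- attn$d_h
  m <- nrow(cache$C); D <- length(de)
  dWo <- outer(fw$o, de); dbo <- de
  do_ <- drop(attn$Wo %*% de)
  dq <- numeric(D)
  dK <- matrix(0, m, D); dV <- matrix(0, m, D)
  for (h in seq_len(H)) {
    idx <- ((h - 1L) * dh + 1L):(h * dh)
    w <- fw$weights[h, ]
    doh <- do_[idx]
    dV[, idx] <- w %o% doh
    dw <- drop(fw$V[, idx, drop = FALSE] %*% doh)
    ds <- w * (dw - sum(w * dw))
    dq[idx] <- drop(ds %*% fw$K[, idx, drop = FALSE]) / sqrt(dh)
    dK[, idx] <- (ds %o% fw$q[idx]) / sqrt(dh)
  }
  grads <- list(Wq = outer(cache$g, dq), Wk = crossprod(cache$C, dK),
                Wv = crossprod(cache$C, dV), Wo = dWo,
                bq = dq, bk = colSums(dK), bv = colSums(dV), bo = dbo)
  dC <- dK %*% t(attn$Wk) + dV %*% t(attn$Wv)
  dg <- drop(attn$Wq %*% dq)
  list(grads = grads, dg = dg, dC = dC)
}

# ---- TextLSTM ---------------------------------------------------------

lstm_forward_batch <- function(batch, emb, weights, config, train = FALSE) {
  B <- batch$B; Lb <- batch$Lb
  H <- config$hidden_dim; D <- config$embed_dim
  E <- emb$E
  dirs <- list(fwd = seq_len(Lb), bwd = rev(seq_len(Lb)))
  caches <- list()
  states <- array(0, c(B, Lb, 2L * H))
  for (d in names(dirs)) {
    p <- weights$lstm[[d]]
    ord <- dirs[[d]]
    h <- matrix(0, B, H); cc <- matrix(0, B, H)
    gates <- array(0, c(B, Lb, 4L * H))
    cs <- array(0, c(B, Lb, H))
    hs <- array(0, c(B, Lb, H))
    bias <- p$b_ih + p$b_hh
    for (step in seq_len(Lb)) {
      l <- ord[step]
      x <- E[((l - 1L) * B + 1L):(l * B), , drop = FALSE]
      alive <- batch$lens >= l
      z <- sweep(x %*% p$Wx + h %*% p$Wh, 2L, bias, "+")
      i <- sigmoid(z[, seq_len(H), drop = FALSE])
      f <- sigmoid(z[, H + seq_len(H), drop = FALSE])
      g <- tanh(z[, 2L * H + seq_len(H), drop = FALSE])
      o <- sigmoid(z[, 3L * H + seq_len(H), drop = FALSE])
      c_new <- f * cc + i * g
      h_new <- o * tanh(c_new)
      cc[alive, ] <- c_new[alive, , drop = FALSE]
      h[alive, ] <- h_new[alive, , drop = FALSE]
      gates[, l, ] <- cbind(i, f, g, o)
      cs[, l, ] <- cc
      hs[, l, ] <- h
      sl <- if (d == "fwd") seq_len(H) else H + seq_len(H)
      states[alive, l, sl] <- h[alive, , drop = FALSE]
    }
    caches[[d]] <- list(gates = gates, cs = cs, hs = hs)
  }
  # temporal max pool over real positions only
  pooled <- matrix(-Inf, B, 2L * H)
  poolarg <- matrix(NA_integer_, B, 2L * H)
  for (l in seq_len(Lb)) {
    alive <- batch$lens >= l
    slab <- matrix(states[, l, ], nrow = B)
    upd <- alive & (slab > pooled)
    pooled[upd] <- slab[upd]
    poolarg[upd] <- l
  }
  pooled[!is.finite(pooled)] <- 0
  logits <- drop(pooled %*% weights$fc_w) + weights$fc_b
  list(logits = logits, pooled = pooled, poolarg = poolarg, caches = caches)
}

lstm_backward_batch <- function(batch, emb, fw, dlogits, weights, config) {
  B <- batch$B; Lb <- batch$Lb
  H <- config$hidden_dim; D <- config$embed_dim
  gr <- new_grads(weights, config)
  gr$fc_b <- sum(dlogits)
  gr$fc_w <- drop(crossprod(fw$pooled, dlogits))
  dpool <- outer(dlogits, weights$fc_w)      # B x 2H
  dE <- matrix(0, nrow(emb$E), D)
  dirs <- list(fwd = seq_len(Lb), bwd = rev(seq_len(Lb)))
  for (d in names(dirs)) {
    p <- weights$lstm[[d]]
    cache <- fw$caches[[d]]
    sl <- if (d == "fwd") seq_len(H) else H + seq_len(H)
    # scatter pooled gradient to argmax timesteps
    dh_inject <- array(0, c(B, Lb, H))
    pa <- fw$poolarg[, sl, drop = FALSE]
    dp <- dpool[, sl, drop = FALSE]
    live <- which(!is.na(pa) & dp != 0)
    if (length(live) > 0L) {
      bidx <- ((live - 1L) %% B) + 1L
      hidx <- ((live - 1L) %/% B) + 1L
      dh_inject[cbind(bidx, pa[live], hidx)] <- dp[live]
    }
    ord <- dirs[[d]]
    dh <- matrix(0, B, H); dc <- matrix(0, B, H)
    dWx <- matrix(0, D, 4L * H); dWh <- matrix(0, H, 4L * H)
    db <- numeric(4L * H)
    for (step in rev(seq_len(Lb))) {
      l <- ord[step]
      alive <- batch$lens >= l
      if (!any(alive)) next
      dh_t <- dh + matrix(dh_inject[, l, ], nrow = B)
      g4 <- matrix(cache$gates[, l, ], nrow = B)
      i <- g4[, seq_len(H), drop = FALSE]
      f <- g4[, H + seq_len(H), drop = FALSE]
      g <- g4[, 2L * H + seq_len(H), drop = FALSE]
      o <- g4[, 3L * H + seq_len(H), drop = FALSE]
      c_t <- matrix(cache$cs[, l, ], nrow = B)
      tc <- tanh(c_t)
      c_prev <- if (step > 1L) matrix(cache$cs[, ord[step - 1L], ], nrow = B)
                else matrix(0, B, H)
      h_prev <- if (step > 1L) matrix(cache$hs[, ord[step - 1L], ], nrow = B)
                else matrix(0, B, H)
      do_ <- dh_t * tc * o * (1 - o)
      dc_t <- dc + dh_t * o * (1 - tc^2)
      di <- dc_t * g * i * (1 - i)
      df <- dc_t * c_prev * f * (1 - f)
      dg <- dc_t * i * (1 - g^2)
      dz <- cbind(di, df, dg, do_)
      dz[!alive, ] <- 0
      x <- emb$E[((l - 1L) * B + 1L):(l * B), , drop = FALSE]
      dWx <- dWx + crossprod(x, dz)
      dWh <- dWh + crossprod(h_prev, dz)
      db <- db + colSums(dz)
      dE[((l - 1L) * B + 1L):(l * B), ] <-
        dE[((l - 1L) * B + 1L):(l * B), , drop = FALSE] + dz %*% t(p$Wx)
      dh_new <- dz %*% t(p$Wh)
      dc_new <- dc_t * f
      # dead lanes pass their gradient through unchanged
      dh[alive, ] <- dh_new[alive, , drop = FALSE]
      dc[alive, ] <- dc_new[alive, , drop = FALSE]
    }
    gr$lstm[[d]]$Wx <- dWx
    gr$lstm[[d]]$Wh <- dWh
    gr$lstm[[d]]$b_ih <- db
    gr$lstm[[d]]$b_hh <- db
  }
  backprop_embedding(batch, emb, dE, gr, weights, config)
}

# ---- gradient containers and Adam ------------------------------------

new_grads <- function(weights, config) {
  zero_like <- function(x) {
    if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else numeric(length(x))
  }
  gr <- list(embed = zero_like(weights$embed),
             fc_w = zero_like(weights$fc_w), fc_b = 0)
  if (!is.null(weights$scalenum)) {
    gr$scalenum <- list(a = zero_like(weights$scalenum$a),
                        b = zero_like(weights$scalenum$b))
  }
  if (!is.null(weights$attn)) {
    gr$attn <- lapply(weights$attn[c("Wq", "Wk", "Wv", "Wo",
                                     "bq", "bk", "bv", "bo")], zero_like)
  }
  if (!is.null(weights$conv)) {
    gr$conv <- lapply(weights$conv,
                      function(cv) list(W = zero_like(cv$W),
                                        b = zero_like(cv$b)))
  }
  if (!is.null(weights$lstm)) {
    gr$lstm <- lapply(weights$lstm, function(p) lapply(p, zero_like))
  }
  gr
}

tree_add <- function(a, b) {
  if (is.list(a)) {
    for (nm in names(b)) a[[nm]] <- tree_add(a[[nm]], b[[nm]])
    a
  } else a + b
}

adam_init <- function(gr) {
  zero <- function(x) if (is.list(x)) lapply(x, zero) else x * 0
  list(m = zero(gr), v = zero(gr), t = 0L)
}

# One Adam step over the weight tree; returns the updated weights/state.
adam_step <- function(weights, gr, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- function(w, g, m, v) {
    if (is.list(g)) {
      for (nm in names(g)) {
        r <- upd(w[[nm]], g[[nm]], m[[nm]], v[[nm]])
        w[[nm]] <- r$w; m[[nm]] <- r$m; v[[nm]] <- r$v
      }
      return(list(w = w, m = m, v = v))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    w <- w - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    list(w = w, m = m, v = v)
  }
  # walk only gradient leaves so non-learnable fields stay untouched
  for (nm in names(gr)) {
    r <- upd(weights[[nm]], gr[[nm]], state$m[[nm]], state$v[[nm]])
    weights[[nm]] <- r$w
    state$m[[nm]] <- r$m
    state$v[[nm]] <- r$v
  }
  weights$embed[1L, ] <- 0                   # padding row stays zero
  list(weights = weights, state = state)
}
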