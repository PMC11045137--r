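test_that("parameter accounting matches the closed forms", {
  cnn <- textcnn_config()
  lstm <- textlstm_config()
  pb <- count_parameters(cnn, vocab_size = 9408L, mode = "attntonum")
  expect_identical(pb$attention, 10200L)
  expect_identical(pb$post_embed, 24553L)
  expect_identical(pb$embed, 470400L)
  pbl <- count_parameters(lstm, vocab_size = 9408L, mode = "attntonum")
  expect_identical(pbl$post_embed, 98737L)
  expect_identical(pbl$post_embed - pb$post_embed, 74184L)
  # direct parameterization of 5 slope/offset vector pairs
  expect_identical(pb$number_embedding, 500L)
  expect_identical(count_parameters(cnn, 11011L, "basic")$number_embedding, 0L)
  expect_identical(count_parameters(cnn, 11011L, "basic")$attention, 0L)

  # counts equal direct enumeration of learnable scalars, for any config
  set.seed(4)
  pp <- fixture_prepped()
  for (mode in c("basic", "attntonum")) {
    v <- build_vocab(pp, mode)
    for (cfg in list(textcnn_config(max_len = 32L),
                     textlstm_config(max_len = 32L, hidden_dim = 7L))) {
      w <- init_weights(v, cfg)
      learnable <- length(w$embed) + length(w$fc_w) + 1L +
        (if (!is.null(w$scalenum)) length(w$scalenum$a) + length(w$scalenum$b) else 0L) +
        (if (!is.null(w$attn)) length(unlist(w$attn[c("Wq","Wk","Wv","Wo","bq","bk","bv","bo")])) else 0L) +
        (if (!is.null(w$conv)) sum(vapply(w$conv, function(cv) length(cv$W) + length(cv$b), numeric(1))) else 0L) +
        (if (!is.null(w$lstm)) length(unlist(w$lstm)) else 0L)
      expect_identical(count_parameters(cfg, v$size, mode)$total,
                       as.integer(learnable))
    }
  }
})

test_that("TextCNN logit reconstructs exactly from the forward record", {
  set.seed(31)
  pp <- fixture_prepped()
  cfg <- textcnn_config(max_len = 32L)
  v <- build_vocab(pp, "basic")
  w <- init_weights(v, cfg)
  ids <- encode_tokens(pp[[1]], v, cfg$max_len)
  note <- embed_sequence(ids, pp[[1]]$mentions, "basic", w)
  fw <- textcnn_forward(note, w, cfg)
  expect_equal(fw$logit, w$fc_b + sum(w$fc_w * fw$activations),
               tolerance = 1e-12)
  expect_length(fw$activations, 176L)

  # zero weights everywhere: logit is the classification offset
  w0 <- w
  for (si in seq_along(w0$conv)) { w0$conv[[si]]$W[] <- 0; w0$conv[[si]]$b[] <- 0 }
  w0$fc_w[] <- 0; w0$fc_b <- 0.37
  fw0 <- textcnn_forward(note, w0, cfg)
  expect_equal(fw0$logit, 0.37)

  # additivity: doubling one pooled activation moves the logit by w_f * delta
  f <- which(fw$activations > 0)[1]
  acts2 <- fw$activations
  acts2[f] <- 2 * acts2[f]
  relog <- w$fc_b + sum(w$fc_w * acts2)
  expect_equal(relog - fw$logit, w$fc_w[f] * fw$activations[f],
               tolerance = 1e-12)
})

test_that("TextLSTM pools 176-wide states and ignores the padded tail", {
  set.seed(32)
  pp <- fixture_prepped()
  cfg <- textlstm_config(max_len = 32L)
  v <- build_vocab(pp, "basic")
  w <- init_weights(v, cfg)
  ids <- encode_tokens(pp[[1]], v, cfg$max_len)
  note <- embed_sequence(ids, pp[[1]]$mentions, "basic", w)
  fw <- textlstm_forward(note, w, cfg)
  expect_length(fw$pooled, 176L)

  # garbage in padded rows must not change the logit once masked out
  note2 <- note
  pad_rows <- which(!note2$mask)
  note2$emb[pad_rows, ] <- matrix(stats::rnorm(length(pad_rows) * 50),
                                  length(pad_rows), 50)
  note2$emb[pad_rows, ] <- note2$emb[sample(pad_rows), ]
  fw2 <- textlstm_forward(note2, w, cfg)
  expect_equal(fw2$logit, fw$logit)

  # single-token note: the pool equals the one recurrence step, which a
  # hand-rolled gate computation reproduces
  x1 <- stats::rnorm(50)
  one_note <- list(emb = matrix(x1, 1, 50), mask = TRUE)
  fw1 <- textlstm_forward(one_note, w, cfg)
  step <- function(p) {
    z <- drop(x1 %*% p$Wx) + p$b_ih + p$b_hh
    H <- cfg$hidden_dim
    sig <- function(u) 1 / (1 + exp(-u))
    i <- sig(z[1:H]); f <- sig(z[H + 1:H])
    g <- tanh(z[2 * H + 1:H]); o <- sig(z[3 * H + 1:H])
    o * tanh(i * g)
  }
  expect_equal(fw1$pooled, c(step(w$lstm$fwd), step(w$lstm$bwd)),
               tolerance = 1e-12)
})

test_that("model configs round-trip through YAML and JSON files", {
  dir <- withr::local_tempdir()
  yml <- file.path(dir, "cfg.yaml")
  writeLines(c("arch: textcnn", "epochs: 15", "max_len: 512"), yml)
  cfg <- read_model_config(yml)
  expect_s3_class(cfg, "textcnn_config")
  expect_equal(cfg$epochs, 15)
  expect_equal(cfg$max_len, 512)
  expect_equal(cfg$n_kernels, 44L)   # untouched defaults stay

  jsn <- file.path(dir, "cfg.json")
  writeLines('{"arch": "textlstm", "hidden_dim": 16}', jsn)
  cfg2 <- read_model_config(jsn)
  expect_s3_class(cfg2, "textlstm_config")
  expect_equal(cfg2$hidden_dim, 16)
  expect_equal(cfg2$n_filters, 32)

  writeLines(c("arch: textcnn", "bogus: 1"), yml)
  expect_error(read_model_config(yml), "unknown config fields")
})
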