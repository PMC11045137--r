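test_that("per-filter SHAP conserves the logit and centers on the dataset", {
  tr <- trained_separable()
  idx <- tr$split$holdout
  recs <- forward_records(tr$model, tr$prepped[idx])
  dec <- shap_filters(tr$model, recs)
  for (s in dec$samples) {
    expect_equal(dec$phi0 + sum(s$phi), s$logit, tolerance = 1e-5)
  }
  # brute-force oracle: recompute phi from the linear read-out directly
  acts <- do.call(rbind, lapply(recs, function(r) r$activations))
  mu <- colMeans(acts)
  w <- tr$model$weights$fc_w
  expect_equal(dec$phi0, tr$model$weights$fc_b + sum(w * mu))
  expect_equal(dec$samples[[3]]$phi, w * (acts[3, ] - mu))

  # mu is order-invariant
  dec2 <- shap_filters(tr$model, recs[sample(length(recs))])
  expect_equal(dec2$mu, dec$mu)

  # single-sample dataset: activations equal their mean, phi0 is the logit
  dec1 <- shap_filters(tr$model, recs[1])
  expect_true(all(abs(dec1$samples[[1]]$phi) < 1e-12))
  expect_equal(dec1$phi0, recs[[1]]$logit)

  # the additive max-pool argument does not apply to recurrent models
  lstm_model <- tr$model
  lstm_model$config <- textlstm_config()
  expect_error(shap_filters(lstm_model, recs), "TextCNN")
})

test_that("ngram aggregation pools nested spans and conserves phi", {
  toks <- c("creatinine", "4.7", "(H)", "_date_", "glucose", "stable")
  mk <- function(phi, start, size) {
    list(phi = phi, argmax = start, filter_size = size, logit = sum(phi))
  }
  # two disjoint spans stay separate
  s <- mk(c(0.5, -0.2), c(1L, 5L), c(2L, 2L))
  tab <- aggregate_ngrams(s, toks)
  expect_equal(nrow(tab), 2L)
  expect_setequal(tab$ngram, c("creatinine 4.7", "glucose stable"))

  # a unigram inside a passing trigram folds into the trigram
  s2 <- mk(c(0.3, 0.4), c(2L, 1L), c(1L, 3L))
  tab2 <- aggregate_ngrams(s2, toks)
  expect_equal(nrow(tab2), 1L)
  expect_equal(tab2$ngram, "creatinine 4.7 (H)")
  expect_equal(tab2$phi, 0.7)

  # identical spans pool
  s3 <- mk(c(0.1, 0.2, -0.05), c(2L, 2L, 4L), c(2L, 2L, 2L))
  tab3 <- aggregate_ngrams(s3, toks)
  expect_equal(sort(tab3$phi), sort(c(0.3, -0.05)))

  # conservation and single assignment on random span sets
  set.seed(47)
  for (rep in 1:20) {
    n <- sample(3:12, 1)
    size <- sample(c(1L, 2L, 3L, 5L), n, replace = TRUE)
    start <- vapply(size, function(k) sample(length(toks) - k + 1L, 1L),
                    integer(1))
    phi <- rnorm(n)
    tabr <- aggregate_ngrams(mk(phi, start, size), toks)
    expect_equal(sum(tabr$phi), sum(phi), tolerance = 1e-12)
    expect_equal(sum(tabr$n_filters), n)
  }

  # padding winners are collected under the <pad> feature
  s4 <- mk(c(0.2, 0.3), c(1L, NA), c(2L, 3L))
  tab4 <- aggregate_ngrams(s4, toks)
  expect_true("<pad>" %in% tab4$ngram)
  expect_equal(sum(tab4$phi), 0.5)
})

test_that("dataset-mean SHAP-N averages over all samples and ranks", {
  t1 <- data.frame(ngram = c("a b", "c"), start = c(1L, 3L),
                   size = c(2L, 1L), phi = c(0.4, 0.1), n_filters = c(1L, 1L))
  t2 <- data.frame(ngram = "a b", start = 1L, size = 2L, phi = 0.2,
                   n_filters = 2L)
  tab <- mean_shapn(list(t1, t2))
  expect_equal(tab$ngram[1], "a b")
  expect_equal(tab$phi[tab$ngram == "a b"], 0.3)       # (0.4 + 0.2) / 2
  expect_equal(tab$phi[tab$ngram == "c"], 0.05)        # absent sample counts 0
  expect_equal(tab$support[tab$ngram == "a b"], 2L)
  single <- mean_shapn(list(t1))
  expect_equal(single$phi[single$ngram == "a b"], 0.4)
})

test_that("embedding correlations match the Pearson definition", {
  set.seed(53)
  pp <- fixture_prepped()
  cfg <- textcnn_config(max_len = 32L)
  v <- build_vocab(pp, "attntonum")
  w <- init_weights(v, cfg)
  model <- structure(list(weights = w, vocab = v, config = cfg,
                          mode = "attntonum", left = 1L, right = 2L),
                     class = "nr_model")
  expect_equal(embedding_correlation("BUN 10.0 (L)", "BUN 10.0 (L)", model,
                                     "scalenum"), 1)
  # numbers share the placeholder row before the numeric path: rho = 1
  expect_equal(embedding_correlation("BUN 3.4 (L)", "creatinine 3.8 (H)",
                                     model, "rooc"), 1)
  v1 <- scalenum_embed(3.4, w$scalenum)
  v2 <- scalenum_embed(25.0, w$scalenum)
  expect_equal(embedding_correlation("BUN 3.4 (L)", "BUN 25.0 (H)", model,
                                     "scalenum"), cor(v1, v2))
  expect_equal(cor(v1, -v1), -1)
  expect_error(embedding_correlation("BUN none", "BUN 3.4 (L)", model),
               "no in-context")
})

test_that("attention probes return row-stochastic weights over the window", {
  set.seed(59)
  pp <- fixture_prepped()
  cfg <- textcnn_config(max_len = 32L)
  v <- build_vocab(pp, "attntonum")
  w <- init_weights(v, cfg)
  model <- structure(list(weights = w, vocab = v, config = cfg,
                          mode = "attntonum", left = 1L, right = 2L),
                     class = "nr_model")
  W <- attention_weights("_date_ creatinine 6.3 (H)", model)
  expect_equal(dim(W), c(5L, 4L))
  expect_equal(unname(rowSums(W)), rep(1, 5))
  expect_identical(colnames(W), c("_date_", "creatinine", "6.3", "(H)"))
  expect_error(attention_weights("no numbers here", model), "no in-context")
})
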