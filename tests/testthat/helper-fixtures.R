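# Small shared fixtures, built in code.

# Training trajectories are numerically chaotic: reduction order inside a
# threaded BLAS perturbs the last float bit and, over epochs, the fitted
# weights. Pin BLAS to one thread so suite results are reproducible
# run-to-run regardless of host core count.
Sys.setenv(OPENBLAS_NUM_THREADS = "1", OMP_NUM_THREADS = "1",
           MKL_NUM_THREADS = "1")

fixture_prepped <- function() {
  texts <- c("visit one BUN 24.0 (H) glucose 140.0 ok",
             "creatinine .7 (L) 03/04/18 Cl 93.0 (L) fine stable",
             "platelets 250000 BUN 12.0 (L) creatinine 2.5 (H) end",
             "no labs today just filler words here")
  prep_corpus(data.frame(note_id = paste0("n", seq_along(texts)),
                         text = texts))
}

# random token sequences for property-style checks
random_tokens <- function(n, p_num = 0.25, p_kw = 0.1) {
  pool <- c("alpha", "beta", "gamma", "(H)", "(L)", "_date_")
  vapply(seq_len(n), function(i) {
    u <- stats::runif(1)
    if (u < p_num) {
      format(round(stats::runif(1, 0.1, 2000), 1))
    } else if (u < p_num + p_kw) {
      sample(c("BUN", "creatinine", "-bun"), 1)
    } else sample(pool, 1)
  }, character(1))
}

# brute-force window scan used as the in-context oracle
brute_in_context <- function(tokens, position, keywords = c("bun", "creatinine"),
                             left = 1L, right = 2L) {
  for (k in seq_along(tokens)) {
    tk <- tolower(tokens[k])
    is_kw <- any(tk == keywords | endsWith(tk, paste0("-", keywords)))
    if (is_kw && k != position && position >= k - left &&
        position <= k + right)

      return(TRUE)
  }
  FALSE
}

# a tiny trained CNN on the separable corpus, cached per session
trained_separable <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sep <- generate_separable_corpus(n_notes = 150, seed = 3)
      pp <- prep_corpus(sep$notes)
      y <- sep$labels$label
      sp <- stratified_split(y, seed = 1)
      cfg <- textcnn_config(max_len = 64L, epochs = 70L, batch_size = 32L)
      m <- fit_model(pp, y, sp$train, sp$validation, cfg, "basic", seed = 1)
      cache <<- list(model = m, prepped = pp, labels = y, split = sp)
    }
    cache
  }
})
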