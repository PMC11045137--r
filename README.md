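# noterisk

Predicting surgical outcomes from a single free-text consult note, with
numeric tokens embedded by **magnitude** instead of by surface form.

## The problem

Classifiers over clinical notes are asked to use values like
`BUN 24.0 (H)` or `creatinine .7 (L)` — renal-function labs that strongly
predict the composite outcome of operative mortality or major morbidity
after coronary artery bypass grafting. Standard tokenization makes every
numeric literal an opaque word: `1.7` and `1.8` are as unrelated as `1.7`
and `94`, and on a corpus of a couple thousand notes most held-out values
were never seen in training. `noterisk` implements a family of numeric
embedding strategies for this problem, the classifiers and experiment
harness to evaluate them, a paired sign-flip permutation test for model
comparison, and exact ngram-level SHAP attribution:

* **ROOC** — Replace Out-Of-Context numbers: any number outside a keyword
  context window (one token left / two right of `bun` or `creatinine`)
  becomes `_INUM_` (≤ 1000) or `_lgnum_` (> 1000).
* **ScaleNum** — in-context numbers are embedded as
  `ĝ(x) = Σₖ₌₁⁵ σ(aₖ · log(clamp(x, 1, 1000)) + bₖ)` with learned
  dimension-50 vectors `aₖ, bₖ`, so similar magnitudes land close in
  embedding space regardless of surface form.
* **AttnToNum** — the ScaleNum embedding is refined by 5-head scaled
  dot-product attention over the 4-token keyword window (query: the
  number's ScaleNum embedding; keys/values: the window embeddings), so
  `BUN 12.0` and `creatinine 12.0` can separate despite equal magnitude.
* **TextCNN / TextLSTM** heads: dim-50 embeddings; filter sizes
  (1, 2, 3, 5) × 44 kernels with a note-wide max pool, or a bi-LSTM with
  hidden size 88 per direction and a temporal max pool; both end in a
  176-wide linear read-out `logit = w₀ + Σ_f w_f a_f`. Training is Adam /
  binary cross-entropy, implemented entirely in package R code (no
  neural-framework dependency) and verified by finite-difference gradient
  checks.
* **SHAP-N** — because the max pool makes the TextCNN logit additive over
  filters, `φ_{f,s} = w_f (a_{s,f} − μ_f)` is an exact Shapley
  decomposition; filter values pool onto their argmax ngram spans with
  nested spans folded into the longest passing span.
* **Sign-flip permutation test** — paired per-split AUC gaps `gv = A − T`,
  `t = Σ gv`, compared against random sign flips (35,000 Monte Carlo
  draws, or exact enumeration of all 2¹⁰ sign patterns).

The original study corpus is protected health information, so the package
ships a seeded generator of synthetic surgical-consult-style notes whose
binary outcome is logistic in the log lab values, targeting 32.6%
prevalence; every end-to-end test runs against it.

## Worked example

```r
library(noterisk)

corp <- generate_corpus(synth_config(n_notes = 400L), seed = 42)
corp
#> <synth_corpus> 400 synthetic notes, prevalence 0.340 (target 0.326)

pp <- prep_corpus(corp$notes)
y  <- corp$labels$label
sp <- stratified_split(y, seed = 1)
lengths(sp[c("train", "validation", "holdout")])
#>      train validation    holdout
#>        289         51         60

cfg <- textcnn_config(max_len = 256L, epochs = 30L)
model <- fit_model(pp, y, sp$train, sp$validation, cfg,
                   mode = "scalenum", seed = 1)
model
#> <nr_model> textcnn / scalenum, vocab 328, 30 epochs (final loss 0.6134)

auc_score(predict(model, pp[sp$holdout]), y[sp$holdout])
#> [1] 0.705

cal <- calibrate(model$val_preds, y[sp$validation])
round(c(slope = cal$slope, intercept = cal$intercept), 3)
#>     slope intercept
#>     3.632    -0.923
```

The holdout AUC of 0.705 is the probability that a random positive-outcome
note outranks a random negative one under this (deliberately small,
briefly trained) ScaleNum model; chance is 0.5. The calibration fit maps
binned validation predictions to observed outcome rates — a slope far
from 1 at this scale simply says the under-trained probabilities are
compressed relative to the observed rates.

Comparing the published per-split holdout AUC rows of the two extreme
embedding modes:

```r
tab <- benchmark_aucs("textcnn")
cmp <- compare_modes(tab, "attntonum", "basic", seed = 1)
cmp$mc
#> sign-flip permutation test (monte_carlo, 35000 assignments)
#>   t = 0.3290, one-sided p = 0.0022, two-sided p = 0.003714
cmp$exact
#> sign-flip permutation test (exact, 1024 assignments)
#>   t = 0.3290, one-sided p = 0.001953, two-sided p = 0.003906
```

The attention-refined embedding beats basic tokenization by a summed AUC
gap of 0.329 across the ten paired splits; only 4 of the 1024 possible
sign assignments produce a gap that extreme, a two-sided p of about
0.004.

```r
count_parameters(textcnn_config(), vocab_size = 9408, mode = "attntonum")
#> embed 470,400 | number embedding 500 | attention 10,200 | post-embed 24,553 | total 505,653
```

A command-line front end over the same functions lives at
`inst/scripts/noterisk` (`simulate`, `train`, `summarize`, `compare`).

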