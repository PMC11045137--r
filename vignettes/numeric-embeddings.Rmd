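---
title: "Magnitude-aware numeric embeddings for clinical-note classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Magnitude-aware numeric embeddings for clinical-note classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noterisk)
```

## The problem

Preoperative surgical consult notes carry the information a clinician would
use to judge the risk of the composite outcome of operative mortality or
major morbidity after coronary artery bypass grafting: renal-function labs
("BUN 24.0 (H)", "creatinine .7 (L)"), symptoms, and history. A text
classifier trained on such notes faces a specific representational problem:
standard tokenization treats every numeric surface form as an opaque word,
so 1.7 and 1.8 are as unrelated as 1.7 and 94. On small corpora (a couple
of thousand notes) the model never sees enough repeats of each value to
recover the underlying ordering. `noterisk` implements a family of
embedding strategies that inject number *magnitude* directly into the
representation, plus everything needed to evaluate and interrogate them.

## The embedding pipeline

Preprocessing tokenizes on whitespace while preserving three token shapes
that matter here -- decimals including the leading-dot clinical style
(".7"), parenthesized lab flags ("(H)", "(L)"), and date strings, which
are replaced by a `_date_` tag. A number is **in context** when it lies
within one token to the left or two tokens to the right of a lab keyword
(defaults `bun`, `creatinine`, matched case-insensitively and tolerant of
hyphen-fused forms such as `_date_-bun`). These window extents are
deliberate domain knowledge: clinicians transcribe labs as
`<keyword> <value> (<flag>)`.

Four modes build on this:

* **basic** -- numbers are ordinary vocabulary entries.
* **rooc** -- *Replace Out-Of-Context numbers*: any number outside every
  keyword window becomes `_INUM_` (value at or below 1000) or `_lgnum_`
  (above 1000). Sporadic vitals and doses stop inflating the vocabulary
  while the lab signal stays intact. Values exactly 1000 go to `_INUM_`;
  the boundary is arbitrary and the choice only needs to be fixed.
* **scalenum** -- in-context numbers bypass the lookup table entirely.
  Each is embedded as `sum_{k=1}^{5} sigmoid(a_k log(clamp(x, 1, 1000)) + b_k)`
  with learned slope/offset vectors `a_k, b_k` of the embedding dimension
  (50). The clamp guarantees a finite log and costs nothing for renal labs,
  which live well inside [1, 1000]; the closed form
  `x^a e^b / (x^a e^b + 1)` is algebraically identical and is used as a
  test oracle. Summing five transforms lets different dimensions saturate
  at different scales, so nearby magnitudes land near each other while the
  representation stays bounded in (0, 5).
* **attntonum** -- the ScaleNum embedding is refined by 5-head scaled
  dot-product attention (head dimension 10) whose query is the number's
  ScaleNum embedding and whose keys/values are the embeddings of the
  4-token keyword window (the number's own slot holding its ScaleNum
  embedding). The attention output *replaces* the ScaleNum row -- the
  pipeline is sequential and no residual connection is used. This is what
  lets "BUN 12.0" and "creatinine 12.0" -- near-identical magnitudes with
  nearly opposite clinical meanings -- separate.

Score scaling by `1/sqrt(d_h)` is the standard stabilization; it is a
design choice here, as is the initialization (small-variance normal for
`a_k, b_k` so the numeric embedding begins near-constant, uniform
fan-in for the attention projections). An identity-preserving attention
start (value/output projections at the identity) was evaluated, on the
argument that a random-projection start scrambles the magnitude signal
the refined row replaces, but measured no better at the package's
experiment scales, so the conventional fan-in start stands.

In `scalenum`/`attntonum` modes the number's *surface form* never enters
the vocabulary; its position is encoded with a reserved placeholder id and
the embedding row is overridden. Out-of-context numbers are tagged exactly
as in `rooc`.

## Classifiers

**TextCNN**: dimension-50 embeddings, four valid-convolution filter banks
of sizes (1, 2, 3, 5) with 44 kernels each (176 filters), rectified
linear activation, a note-wide max pool per filter, dropout 0.5 on the
pooled vector, and a linear read-out
`logit = w_0 + sum_f w_f a_f`. **TextLSTM** swaps the convolution for a
bidirectional LSTM with hidden dimension 88 per direction (output width
176, chosen so the classification layer matches TextCNN's), temporal max
pool, no dropout, 50 epochs instead of 100. Optimization is Adam
(learning rate 3.5e-4, batch size 64, binary cross-entropy); the
optimizer and loss are unstated in the source description and Adam/BCE is
the field default for this architecture family. There is no early
stopping: the fixed epoch budget is part of the protocol and final-epoch
weights are used.

Parameter accounting is exact and closed-form (`count_parameters()`):
the attention block is 4 x (50 x 50 + 50) = 10,200; the CNN post-embedding
layers 50 x (1+2+3+5) x 44 + 4 x 44 + 177 = 24,553; the bi-LSTM
2 x (4 x 88 x (50+88) + 2 x 4 x 88) + 177 = 98,737 (two offset vectors per
gate bank -- the convention that reproduces the published count). The
direct ScaleNum parameterization is 5 x (50 + 50) = 500 learnable scalars;
the published table prints 600 for this block without itemizing it, and we
implement the equations as written.

Padded positions are handled so they carry no information: the padding
embedding row is frozen at zero, convolution windows lying wholly in the
padded tail reduce to the filter offset (summarized by a single candidate
in the max), and the LSTM recurrence and pool are masked to real tokens.
The masked pool makes the logit invariant to the padded tail, which is
asserted in the tests.

Everything is trained by package-internal batched forward/backward passes
on BLAS matrix operations -- there is no neural framework dependency. The
backward pass of every layer (convolution through the max pool, the
bidirectional recurrence, attention, ScaleNum, embedding scatter) is
verified against central finite differences in the test suite.

## Experiment harness

Each experiment draws a stratified split: 15% holdout, then 15% of the
remainder for validation (round-half-away totals, largest-remainder
per-class allocation -- 1738 notes give 261/222/1255). Splits are shared
across embedding modes and architectures so comparisons are paired.
Validation predictions are binned at 0.1 resolution, and OLS of observed
outcome rate on mean bin prediction gives a calibration slope and
intercept (identity with a warning when fewer than two bins are
occupied). Holdout AUC is the Mann-Whitney statistic with midrank ties.
Because calibration is affine, AUC is computed on the raw scores --
clipping calibrated values into [0, 1] would only create spurious ties.
Row summaries report the mean, the sample variance, and a 95% percentile
bootstrap CI of the mean (2000 resamples); the interval construction
behind the published CIs is unstated, so the bootstrap is our choice.

## Sign-flip permutation comparison

For two modes evaluated on the same 10 splits, the gap vector
`gv = A - T` and its sum `t` are compared against mock sums obtained by
randomly flipping each element's sign: `m = sn . gv`. With 35,000 Monte
Carlo draws, `p1 = (#{t <= m} + 1) / (N + 1)` and
`p2 = (#{t <= |m|} + 1) / (N + 1)` (non-strict comparisons, i.e. ties
count). Because the experiment count is 10, the full enumeration of all
2^10 = 1024 sign patterns is cheap, and `permutation_test_exact()`
reports the exact proportions `count / 2^n` -- the identity pattern always
counts, so the p-value is never zero and needs no add-one shift. The
sampler is checked against the enumeration in the tests, and the
enumeration is the reference for the published comparisons.

## SHAP-N attribution

For TextCNN the max pool makes the logit an exact additive function of
176 scalar activations, so Shapley values need no sampling: with
`mu_f` the dataset-mean activation of filter `f`,
`phi_{f,s} = w_f (a_{s,f} - mu_f)` and
`phi_0 = w_0 + sum_f w_f mu_f` reconstruct every logit exactly. The
dataset defining `mu_f` is the split being explained (holdout by
default). Each filter's argmax window is a token span; identical spans
pool, and spans nested inside a longer passing span fold into it (ties:
longer span, then leftmost), so each filter is assigned exactly once and
conservation survives aggregation. The set-union merging of merely
*overlapping* spans is implemented behind `merge_overlaps = FALSE`
because it smears long runs into uninterpretable features. Dataset-level
`phi_n` averages over **all** samples, absent samples contributing zero
-- the alternative (averaging over supporting samples only) inflates rare
ngrams; the support count is reported alongside. Attribution for the
LSTM is refused: without the additive structure the decomposition is not
exact.

## The synthetic corpus

The study corpus is protected health information and cannot ship, so the
generator emulates the statistical structure the methods exploit, and all
end-to-end claims in this package are claims about that structure:

* BUN ~ lognormal(median 18, sdlog 0.5), creatinine ~ lognormal(median
  1.0, sdlog 0.4) -- strictly positive, right-skewed, straddling the
  transcription cutoffs (BUN high above 20, creatinine high above 1.0) so
  both flags occur often.
* Exactly one BUN and one creatinine mention per note, transcribed as
  `<keyword> <value> (<flag>)` with values at one decimal and the
  clinical leading-dot style below 1.
* Nuisance structure: filler sentences, optional bulleted symptom lists,
  0-3 dates, and sporadic out-of-context lab/vital numbers in both the
  `_INUM_` and `_lgnum_` ranges.
* Outcome probability `logistic(beta0 + 1.2 zB + 1.6 zC)` on the
  standardized log lab values, with `beta0` bisected so mean probability
  hits the target prevalence 0.326. Log-value dependence is deliberate:
  it is exactly the signal a log-scaling embedding should capture, and
  the creatinine coefficient is larger so context (which keyword governs
  the number) matters beyond magnitude. A `flag_only` switch moves the
  signal onto the H/L flags to stress the attention path, and zero
  coefficients give a null corpus for calibration of chance behaviour.

What the generator does **not** emulate: clinical language, section
structure, negation, misspellings, correlated comorbidities, or any
realistic dependence between filler text and outcome. Passing end-to-end
tests therefore demonstrates that the implementation learns the kinds of
numeric/contextual signal the methods target -- not clinical-grade
performance on real notes.

## Problem sizes and numerical choices

The packaged experiments run at reduced scale chosen to keep the full
suite comfortably reproducible on one CPU: 1000-note corpora, a 512-token
length cutoff (synthetic notes are far shorter than real consult notes),
15 training epochs, and 5 experiment splits for the mode-ranking check;
the separable and null controls use 150-300 notes. The published-table
analyses (permutation tests, summary arithmetic, parameter accounting)
run at full fidelity -- they depend only on printed inputs and
architecture arithmetic. Other numerical choices: softmax scores are
max-shifted before exponentiation; the BCE loss clamps probabilities at
1e-12; ties in the convolution argmax take the earliest position; the
add-one Monte Carlo estimator keeps p-values in (0, 1]; bins
`[0, 0.1), ..., [0.9, 1.0]` close the upper edge.

## Known limitations

* The numeric path requires strictly positive values; zero or negative
  quantities (not meaningful for these labs) are out of scope by design
  of the log-scaling.
* ScaleNum embeds magnitude only; it relies on the classifier (or the
  attention refinement) to supply context.
* The training engine is single-threaded R; it is sized for the package's
  experiment scales, not for production corpora with 3000-token notes.
* With 5 splits the mode ranking is a directional check; distinguishing
  closely matched modes reliably needs the full 10-split protocol and a
  paired test, exactly as the harness implements.
* On the default synthetic corpus the AttnToNum-vs-ScaleNum contrast is a
  statistical tie at the 15-epoch reduced scale: the generated BUN and
  creatinine ranges barely overlap, so keyword context adds little beyond
  magnitude (and convolution filters spanning keyword and number give
  every magnitude-aware mode context access), while the attention
  projections need a longer budget to pay off -- doubling the epochs
  flips the comparison in AttnToNum's favour on splits where it trails.
  ScaleNum-vs-Basic, by contrast, separates cleanly at reduced scale.
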