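round_half_away <- function(x) trunc(x + 0.5 * sign(x))

# Allocate a total of n_take draws across classes proportionally to class
# sizes, using largest remainders to hit the total exactly.
allocate_by_class <- function(class_n, n_take) {
  exact <- class_n * n_take / sum(class_n)
  base <- floor(exact)
  rem <- n_take - sum(base)
  if (rem > 0L) {
    extra <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  as.integer(base)
}

#' Stratified train/validation/holdout split
#'
#' First removes a random `holdout_frac` of the samples as the holdout set,
#' then splits the remainder into validation (`val_frac` of the remainder)
#' and training. Both splits are stratified: each part receives a
#' per-class allocation proportional to the class sizes (largest-remainder
#' rounding), so outcome prevalence is preserved. Totals use
#' round-half-away-from-zero (1738 samples give a 261-sample holdout and a
#' 222-sample validation set). Deterministic for a given seed.
#'
#' @param labels Binary (0/1) outcome vector.
#' @param holdout_frac,val_frac Split fractions (defaults 0.15 and 0.15).
#' @param seed Integer seed.
#' @return Object of class `split_indices`: list with integer index
#'   vectors `train`, `validation`, `holdout` (disjoint, covering) and
#'   `seed`.
#' @export
stratified_split <- function(labels, holdout_frac = 0.15, val_frac = 0.15,
                             seed = 1L) {
  stopifnot(all(labels %in% c(0, 1)))
  if (min(table(labels)) < 2L) {
    stop("need at least 2 samples of each class to stratify")
  }
  set.seed(seed)
  n <- length(labels)
  cls <- list(neg = which(labels == 0), pos = which(labels == 1))
  cls <- lapply(cls, sample)                 # seeded permutation per class
  take <- function(pools, n_take) {
    alloc <- allocate_by_class(lengths(pools), n_take)
    picked <- unlist(Map(function(p, k) p[seq_len(k)], pools, alloc),
                     use.names = FALSE)
    rest <- Map(function(p, k) p[-seq_len(k)], pools, alloc)
    list(picked = sort(picked), rest = rest)
  }
  hold <- take(cls, round_half_away(holdout_frac * n))
  n_rest <- sum(lengths(hold$rest))
  val <- take(hold$rest, round_half_away(val_frac * n_rest))
  structure(list(train = sort(unlist(val$rest, use.names = FALSE)),
                 validation = val$picked, holdout = hold$picked,
                 seed = seed),
            class = "split_indices")
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a random positive is
#' ranked above a random negative, counting ties as one half (midranks).
#'
#' @param preds Numeric scores.
#' @param labels Binary (0/1) labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(preds, labels) {
  stopifnot(length(preds) == length(labels))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(preds)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Calibrate predicted probabilities against observed rates
#'
#' Validation-set predictions are binned at 0.1 resolution
#' (`[0, 0.1), ..., [0.9, 1.0]`, upper bin closed); within each non-empty
#' bin the mean prediction and the observed outcome rate are computed, and
#' an ordinary least-squares line of observed rate on mean prediction
#' gives the calibration slope and intercept. With fewer than two
#' non-empty bins the identity fit is returned with a warning.
#'
#' @param val_preds Predicted probabilities in `[0, 1]`.
#' @param val_labels Binary (0/1) outcomes.
#' @param bin_width Bin resolution (default 0.1).
#' @return Object of class `calibration_fit`: list with `slope`,
#'   `intercept`, and `bins` (data.frame of per-bin mean prediction,
#'   observed rate, and count).
#' @export
calibrate <- function(val_preds, val_labels, bin_width = 0.1) {
  stopifnot(length(val_preds) == length(val_labels),
            all(val_preds >= 0 & val_preds <= 1))
  edges <- seq(0, 1, by = bin_width)
  bin <- findInterval(val_preds, edges, rightmost.closed = TRUE)
  tab <- data.frame(
    mean_pred = tapply(val_preds, bin, mean),
    obs_rate = tapply(as.numeric(val_labels), bin, mean),
    n = as.integer(table(bin)))
  if (nrow(tab) < 2L) {
    warning("fewer than 2 non-empty bins; returning identity calibration")
    return(structure(list(slope = 1, intercept = 0, bins = tab),
                     class = "calibration_fit"))
  }
  fit <- stats::lm(obs_rate ~ mean_pred, data = tab)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]), bins = tab),
            class = "calibration_fit")
}

#' Apply a calibration fit
#'
#' Affine map of probabilities, clipped to `[0, 1]`.
#'
#' @param fit A `calibration_fit`.
#' @param preds Probabilities to calibrate.
#' @return Calibrated probabilities.
#' @export
apply_calibration <- function(fit, preds) {
  pmin(pmax(fit$intercept + fit$slope * preds, 0), 1)
}

#' Run the multi-split experiment harness
#'
#' For each of `n_experiments` stratified splits (shared across all
#' embedding modes and architectures so comparisons are paired), fits the
#' model on the training set, calibrates on the validation set, and
#' records the holdout AUC. Split `i` uses seed `seed + i`, and the fit
#' for each mode/architecture uses the same per-split seed, so any two
#' modes see identical holdout index sets.
#'
#' @param prepped [prep_corpus()] output.
#' @param labels Binary outcome vector aligned with `prepped`.
#' @param modes Character vector of embedding modes to compare.
#' @param architectures Configs to run, as a named list of `nr_config`
#'   objects (default: one TextCNN).
#' @param n_experiments Number of random splits (default 10).
#' @param seed Base seed.
#' @param keep_models Keep each fitted model (memory-heavy).
#' @param verbose Print progress.
#' @return Object of class `nr_experiments`: list with `auc` (named list,
#'   `architecture$mode` -> AUC vector over splits), `calibration` (same
#'   shape, list of `calibration_fit`), `splits`, and optionally `models`.
#' @export
run_experiments <- function(prepped, labels,
                            modes = c("basic", "scalenum", "attntonum"),
                            architectures = list(textcnn = textcnn_config()),
                            n_experiments = 10L, seed = 1L,
                            keep_models = FALSE, verbose = FALSE) {
  modes <- match.arg(modes, embedding_modes(), several.ok = TRUE)
  splits <- lapply(seq_len(n_experiments),
                   function(i) stratified_split(labels, seed = seed + i))
  auc <- list(); calib <- list(); models <- list()
  for (arch in names(architectures)) {
    config <- architectures[[arch]]
    for (mode in modes) {
      key <- paste(arch, mode, sep = "$")
      aucs <- numeric(n_experiments)
      cals <- vector("list", n_experiments)
      for (i in seq_len(n_experiments)) {
        sp <- splits[[i]]
        model <- fit_model(prepped, labels, sp$train, sp$validation,
                           config = config, mode = mode, seed = seed + i)
        cals[[i]] <- calibrate(model$val_preds, labels[sp$validation])
        hold_preds <- predict(model, prepped[sp$holdout])
        # the calibrated holdout probabilities are an affine map of the raw
        # ones, so AUC is computed on the raw scores (clipping at 0/1 would
        # otherwise introduce spurious ties)
        aucs[i] <- auc_score(hold_preds, labels[sp$holdout])
        if (keep_models) models[[paste(key, i, sep = "$")]] <- model
        if (verbose) {
          message(sprintf("%s split %d/%d: holdout AUC %.3f",
                          key, i, n_experiments, aucs[i]))
        }
      }
      auc[[key]] <- aucs
      calib[[key]] <- cals
    }
  }
  structure(list(auc = auc, calibration = calib, splits = splits,
                 models = if (keep_models) models, seed = seed),
            class = "nr_experiments")
}

#' @export
print.nr_experiments <- function(x, ...) {
  cat("<nr_experiments>\n")
  for (key in names(x$auc)) {
    a <- x$auc[[key]]
    cat(sprintf("  %-22s mean AUC %.3f over %d splits\n",
                key, mean(a), length(a)))
  }
  invisible(x)
}

#' Summarize an AUC vector
#'
#' Mean, sample variance (n - 1 denominator), and a seeded 95% percentile
#' bootstrap confidence interval of the mean.
#'
#' @param aucs Numeric vector of per-split AUCs.
#' @param n_boot Bootstrap replicates.
#' @param seed Seed for the bootstrap.
#' @return List with `mean`, `variance`, `ci` (length-2 vector), `n`.
#' @export
summarize_aucs <- function(aucs, n_boot = 2000L, seed = 1L) {
  stopifnot(length(aucs) >= 2L)
  set.seed(seed)
  boots <- vapply(seq_len(n_boot),
                  function(i) mean(sample(aucs, replace = TRUE)), numeric(1))
  list(mean = mean(aucs), variance = stats::var(aucs),
       ci = unname(stats::quantile(boots, c(0.025, 0.975))),
       n = length(aucs))
}
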