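# Fixed filler material for synthetic surgical consult notes. The language
# is schematic on purpose: the generator emulates the statistical structure
# the models exploit (lab mentions near keywords, sporadic out-of-context
# numbers, dates, bulleted symptom lists), not clinical prose.
synth_symptoms <- c("chest pain", "shortness of breath", "fatigue",
                    "dizziness", "palpitations", "nausea", "diaphoresis",
                    "orthopnea", "leg swelling", "syncope")
synth_fillers <- c(
  "patient presents for preoperative surgical consult",
  "history of present illness reviewed with the patient",
  "denies fever chills or recent infection",
  "past medical history notable for hypertension and hyperlipidemia",
  "medications reviewed and reconciled at this visit",
  "physical exam unremarkable except as noted",
  "plan to proceed with coronary artery bypass grafting",
  "risks benefits and alternatives discussed at length",
  "patient ambulates without assistance",
  "social history negative for current tobacco use",
  "echocardiogram demonstrates preserved ejection fraction",
  "cardiac catheterization shows multivessel disease")
synth_ooc_labs <- c("Cl", "glucose", "sodium", "potassium", "WBC", "Hgb",
                    "platelets", "HR", "BP")

#' Synthetic-corpus configuration
#'
#' Defaults define the study conditions the generator emulates: lab values
#' from strictly positive, right-skewed log-normal distributions whose
#' medians straddle the transcription cutoffs (BUN median 18 against the
#' `> 20` high flag; creatinine median 1.0 against `> 1.0`), a binary
#' outcome whose probability is logistic in the standardized log lab
#' values, and a target outcome prevalence of 32.6%.
#'
#' @param n_notes Number of notes.
#' @param prevalence Target mean outcome probability (default 0.326).
#' @param bun_meanlog,bun_sdlog Log-normal parameters for BUN (median
#'   `exp(meanlog)` = 18 mg/dL).
#' @param cr_meanlog,cr_sdlog Log-normal parameters for creatinine
#'   (median 1.0 mg/dL).
#' @param beta_bun,beta_cr Outcome coefficients on the standardized log
#'   lab values (`beta = 0` for both gives a null-signal corpus).
#' @param flag_only If `TRUE` the outcome depends only on the transcribed
#'   H/L flags, not the magnitudes (stresses the context-attention path).
#' @param n_nuisance Size of the nuisance filler vocabulary.
#' @param len_range Range of filler tokens per note.
#' @param bullet_frac Fraction of notes with a bulleted symptom list.
#' @param max_dates Maximum number of date strings per note.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(n_notes = 1000L, prevalence = 0.326,
                         bun_meanlog = log(18), bun_sdlog = 0.5,
                         cr_meanlog = log(1.0), cr_sdlog = 0.4,
                         beta_bun = 1.2, beta_cr = 1.6,
                         flag_only = FALSE, n_nuisance = 300L,
                         len_range = c(40L, 120L), bullet_frac = 0.35,
                         max_dates = 3L) {
  stopifnot(prevalence > 0, prevalence < 1, n_notes >= 1L)
  structure(list(n_notes = n_notes, prevalence = prevalence,
                 bun_meanlog = bun_meanlog, bun_sdlog = bun_sdlog,
                 cr_meanlog = cr_meanlog, cr_sdlog = cr_sdlog,
                 beta_bun = beta_bun, beta_cr = beta_cr,
                 flag_only = flag_only, n_nuisance = n_nuisance,
                 len_range = len_range, bullet_frac = bullet_frac,
                 max_dates = max_dates),
            class = "synth_config")
}

# Lab-value surface form: one decimal, leading zero dropped below 1
# ("creatinine .7 (L)"), as transcribed in consult notes.
format_lab <- function(x) {
  s <- sprintf("%.1f", x)
  sub("^0\\.", ".", s)
}

format_flag <- function(value, cutoff) {
  if (value > cutoff) "(H)" else "(L)"
}

random_date <- function() {
  sprintf("%02d/%02d/%02d", sample(12, 1), sample(28, 1),
          sample(14:22, 1))
}

nuisance_vocab <- function(config) {
  extra <- max(config$n_nuisance - length(synth_fillers) * 6L, 0L)
  c(unlist(strsplit(synth_fillers, " ")),
    sprintf("term%03d", seq_len(extra)))
}

#' Generate one synthetic consult note
#'
#' The note mixes filler sentences, an optional bulleted symptom list,
#' 0-3 date strings, sporadic out-of-context lab/vital numbers in both
#' the small (`_INUM_`) and large (`_lgnum_`) ranges, and exactly one BUN
#' and one creatinine mention formatted `"<keyword> <value> (<H|L>)"`,
#' with the flag transcribed from the cutoffs (BUN high above 20,
#' creatinine high above 1.0). Consumes the current RNG stream.
#'
#' @param config A `synth_config`.
#' @param bun,creatinine Lab values to embed (drawn by
#'   [generate_corpus()]; any strictly positive values).
#' @return List with `text`, `bun`, `creatinine`.
#' @export
generate_note <- function(config, bun, creatinine) {
  vocab <- nuisance_vocab(config)
  n_fill <- sample(config$len_range[1]:config$len_range[2], 1L)
  words <- sample(vocab, n_fill, replace = TRUE)
  # break filler into sentence-ish chunks
  chunks <- split(words, cumsum(seq_along(words) %% sample(6:12, 1L) == 1L))
  sentences <- vapply(chunks, paste, character(1), collapse = " ")
  sentences <- c(sample(synth_fillers, 2L), sentences)
  if (stats::runif(1) < config$bullet_frac) {
    bullets <- paste("-", sample(synth_symptoms, sample(2:4, 1L)))
    sentences <- append(sentences, bullets, after = 1L)
  }
  n_dates <- sample(0:config$max_dates, 1L)
  for (d in seq_len(n_dates)) {
    sentences <- append(sentences, random_date(),
                        after = sample(length(sentences), 1L))
  }
  # sporadic out-of-context numbers, small and occasionally large
  n_ooc <- sample(1:4, 1L)
  ooc <- vapply(seq_len(n_ooc), function(i) {
    lab <- sample(synth_ooc_labs, 1L)
    if (stats::runif(1) < 0.2) {
      sprintf("%s %d", lab, sample(1500:300000, 1L))
    } else {
      val <- stats::runif(1, 3, 400)
      if (stats::runif(1) < 0.5) {
        sprintf("%s %s (%s)", lab, format_lab(val),
                sample(c("H", "L"), 1L))
      } else sprintf("%s %s", lab, format_lab(val))
    }
  }, character(1))
  labs <- c(
    sprintf("BUN %s %s", format_lab(bun), format_flag(round(bun, 1), 20)),
    sprintf("creatinine %s %s", format_lab(creatinine),
            format_flag(round(creatinine, 1), 1.0)))
  body <- append(sentences, sample(c(ooc, labs)),
                 after = min(2L, length(sentences)))
  list(text = paste(body, collapse = " . "), bun = bun,
       creatinine = creatinine)
}

#' Generate a labeled synthetic corpus
#'
#' Draws per-note BUN and creatinine values, sets each note's outcome
#' probability to `logistic(beta0 + beta_bun * zB + beta_cr * zC)` where
#' `zB`, `zC` are the standardized log lab values (or standardized H/L
#' flags when `flag_only`), tunes the intercept `beta0` by bisection so
#' the mean probability matches the target prevalence, and draws labels
#' Bernoulli from the stored probabilities. Identical seeds give
#' byte-identical corpora.
#'
#' @param config A `synth_config`.
#' @param seed Integer seed.
#' @return Object of class `synth_corpus`: list with `notes` (data.frame
#'   `note_id`, `text`), `labels` (data.frame `note_id`, `label`), and
#'   `truth` (data.frame with the generating BUN/creatinine values and
#'   outcome probabilities).
#' @export
generate_corpus <- function(config = synth_config(), seed = 1L) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(seed)
  n <- config$n_notes
  bun <- stats::rlnorm(n, config$bun_meanlog, config$bun_sdlog)
  cr <- stats::rlnorm(n, config$cr_meanlog, config$cr_sdlog)
  # values are transcribed at one decimal; the truth matches the text
  bun <- pmax(round(bun, 1), 0.1)
  cr <- pmax(round(cr, 1), 0.1)
  if (config$flag_only) {
    zB <- as.numeric(bun > 20)
    zC <- as.numeric(cr > 1.0)
    zB <- (zB - mean(zB)) / max(stats::sd(zB), 1e-8)
    zC <- (zC - mean(zC)) / max(stats::sd(zC), 1e-8)
  } else {
    zB <- (log(bun) - config$bun_meanlog) / config$bun_sdlog
    zC <- (log(cr) - config$cr_meanlog) / config$cr_sdlog
  }
  eta <- config$beta_bun * zB + config$beta_cr * zC
  beta0 <- stats::uniroot(
    function(b0) mean(stats::plogis(b0 + eta)) - config$prevalence,
    interval = c(-30, 30), tol = 1e-10)$root
  prob <- stats::plogis(beta0 + eta)
  labels <- stats::rbinom(n, 1L, prob)
  notes <- vector("character", n)
  for (i in seq_len(n)) {
    notes[i] <- generate_note(config, bun[i], cr[i])$text
  }
  ids <- sprintf("note%05d", seq_len(n))
  structure(list(
    notes = data.frame(note_id = ids, text = notes,
                       stringsAsFactors = FALSE),
    labels = data.frame(note_id = ids, label = labels,
                        stringsAsFactors = FALSE),
    truth = data.frame(note_id = ids, bun = bun, creatinine = cr,
                       prob = prob, beta0 = beta0,
                       stringsAsFactors = FALSE),
    config = config, seed = seed),
    class = "synth_corpus")
}

#' @export
print.synth_corpus <- function(x, ...) {
  cat(sprintf(
    "<synth_corpus> %d synthetic notes, prevalence %.3f (target %.3f)\n",
    nrow(x$notes), mean(x$labels$label), x$config$prevalence))
  invisible(x)
}

#' Generate a separable control corpus
#'
#' Notes containing the marker token `"SICK"` exactly when the label is 1,
#' on top of nuisance filler. A sanity control: any working classifier
#' reaches holdout AUC 1.0.
#'
#' @param n_notes Number of notes.
#' @param prevalence Positive-label fraction.
#' @param seed Integer seed.
#' @return A `synth_corpus` (without lab truth).
#' @export
generate_separable_corpus <- function(n_notes = 200L, prevalence = 0.4,
                                      seed = 1L) {
  set.seed(seed)
  labels <- stats::rbinom(n_notes, 1L, prevalence)
  vocab <- c(unlist(strsplit(synth_fillers, " ")))
  notes <- vapply(seq_len(n_notes), function(i) {
    words <- sample(vocab, sample(15:40, 1L), replace = TRUE)
    if (labels[i] == 1L) {
      words <- append(words, "SICK", after = sample(length(words), 1L))
    }
    paste(words, collapse = " ")
  }, character(1))
  ids <- sprintf("note%05d", seq_len(n_notes))
  structure(list(
    notes = data.frame(note_id = ids, text = notes,
                       stringsAsFactors = FALSE),
    labels = data.frame(note_id = ids, label = labels,
                        stringsAsFactors = FALSE),
    truth = NULL, config = NULL, seed = seed),
    class = "synth_corpus")
}

#' Write a synthetic corpus to delimited files
#'
#' `notes.csv` (note_id, text), `labels.csv` (note_id, label) and
#' `truth.jsonl` (per-note generating values) under `dir`.
#'
#' @param corpus A `synth_corpus`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(corpus$notes, file.path(dir, "notes.csv"),
                   row.names = FALSE)
  utils::write.csv(corpus$labels, file.path(dir, "labels.csv"),
                   row.names = FALSE)
  if (!is.null(corpus$truth)) {
    con <- file(file.path(dir, "truth.jsonl"), "w")
    on.exit(close(con))
    for (i in seq_len(nrow(corpus$truth))) {
      writeLines(jsonlite::toJSON(as.list(corpus$truth[i, ]),
                                  auto_unbox = TRUE, digits = NA), con)
    }
  }
  invisible(dir)
}

#' Read a notes/labels corpus from delimited files
#'
#' @param notes_path CSV with columns `note_id`, `text`.
#' @param labels_path CSV with columns `note_id`, `label`.
#' @return List with `notes` and `labels` data.frames, aligned by
#'   `note_id`.
#' @export
read_corpus <- function(notes_path, labels_path) {
  notes <- utils::read.csv(notes_path, stringsAsFactors = FALSE)
  labels <- utils::read.csv(labels_path, stringsAsFactors = FALSE)
  stopifnot(all(c("note_id", "text") %in% names(notes)),
            all(c("note_id", "label") %in% names(labels)))
  labels <- labels[match(notes$note_id, labels$note_id), ]
  list(notes = notes, labels = labels)
}
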