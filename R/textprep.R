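#' Tokenize clinical-note text
#'
#' Splits free text on whitespace after padding punctuation, while keeping
#' three token shapes intact that carry signal in surgical consult notes:
#' number literals (including leading-dot decimals such as `".7"`),
#' parenthesized lab flags such as `"(H)"` / `"(L)"`, and date strings such
#' as `"03/04/18"`. Hyphen-fused tokens (`"03/04/18-BUN"`) are kept whole.
#'
#' @param text A length-1 character vector; arbitrary UTF-8.
#' @return Character vector of tokens (possibly length 0). No empty-string
#'   tokens are produced and source order is preserved.
#' @examples
#' tokenize_text("BUN 24.0 (H)")
#' tokenize_text("creatinine .7 (L)")
#' @export
tokenize_text <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) return(character(0))
  # shelter parenthesized short flags, e.g. "(H)", "(L)", "(crit)"
  x <- gsub("\\(([A-Za-z]{1,4})\\)", "\x01\\1\x02", text)
  # pad remaining parentheses and hard punctuation
  x <- gsub("([(),;:!?\"\\[\\]{}*&#%=+<>])", " \\1 ", x, perl = TRUE)
  # a period not followed by a digit is sentence punctuation; "24.0" and
  # ".7" survive, trailing periods ("24.0.") are stripped into their own token
  x <- gsub("\\.(?![0-9])", " . ", x, perl = TRUE)
  x <- gsub("\x01", "(", x, fixed = TRUE)
  x <- gsub("\x02", ")", x, fixed = TRUE)
  toks <- strsplit(trimws(x), "\\s+")[[1]]
  toks[nzchar(toks)]
}

#' Replace date tokens with the `_date_` tag
#'
#' Date strings are uninformative for outcome prediction and inflate the
#' vocabulary, so any `d/d/dd`-shaped substring (1-2 digit day and month,
#' 2- or 4-digit year) is replaced by the tag `"_date_"`. The replacement
#' is substring-aware so hyphen-fused forms survive as single tokens:
#' `"03/04/18-BUN"` becomes `"_date_-BUN"`. Sequence length is preserved.
#'
#' @param tokens Character vector of tokens.
#' @return Character vector of the same length.
#' @examples
#' tag_dates(c("creatinine", "5.2", "(H)", "03/05/18"))
#' @export
tag_dates <- function(tokens) {
  gsub("\\b[0-9]{1,2}/[0-9]{1,2}/([0-9]{4}|[0-9]{2})\\b", "_date_", tokens)
}

date_tag <- "_date_"
inum_tag <- "_INUM_"
lgnum_tag <- "_lgnum_"

#' @keywords internal
is_number_token <- function(tokens) {
  grepl("^[0-9]*\\.?[0-9]+$", tokens)
}

#' @keywords internal
parse_number_token <- function(tokens) {
  val <- rep(NA_real_, length(tokens))
  ok <- is_number_token(tokens)
  val[ok] <- as.numeric(tokens[ok])
  val
}

#' @keywords internal
matches_keyword <- function(tokens, keywords) {
  low <- tolower(tokens)
  hit <- rep(NA_character_, length(tokens))
  for (kw in tolower(keywords)) {
    m <- is.na(hit) & (low == kw | endsWith(low, paste0("-", kw)))
    hit[m] <- kw
  }
  hit
}

#' Detect numeric mentions and their keyword context
#'
#' Scans a token sequence for parseable positive numbers and decides, for
#' each, whether it lies in the context window of a lab keyword. A number at
#' position `p` is in context when some keyword occurrence at position `k`
#' satisfies `k - left <= p <= k + right` with `p != k` (defaults: one token
#' to the left of the keyword or two to the right, matching how lab values
#' are transcribed as `"BUN 24.0 (H)"`). Keyword matching is
#' case-insensitive and tolerates a fused leading hyphen (`"_date_-bun"`).
#'
#' @param tokens Character vector of tokens (after [tag_dates()]).
#' @param keywords Non-empty character vector of lab keywords;
#'   default `c("bun", "creatinine")`.
#' @param left,right Non-negative window extents around a keyword.
#' @return A data.frame with one row per numeric mention: `position`
#'   (1-based token index), `value` (positive double), `keyword` (governing
#'   keyword, or `NA` when out of context), `keyword_position` (1-based
#'   index of the governing keyword occurrence, or `NA`), and `in_context`
#'   (logical). When several keyword occurrences cover a number, the nearest
#'   (ties to the earlier position) governs. Pseudo-numbers such as
#'   `"1.2.3"` and zero-valued tokens are not mentions.
#' @examples
#' find_numeric_mentions(c("creatinine", "5.2", "(H)"))
#' find_numeric_mentions(c("Cl", "93.0", "(L)"))
#' @export
find_numeric_mentions <- function(tokens, keywords = c("bun", "creatinine"),
                                  left = 1L, right = 2L) {
  stopifnot(length(keywords) >= 1L, left >= 0L, right >= 0L)
  empty <- data.frame(position = integer(0), value = numeric(0),
                      keyword = character(0), in_context = logical(0),
                      stringsAsFactors = FALSE)
  if (length(tokens) == 0L) return(empty)
  vals <- parse_number_token(tokens)
  pos <- which(!is.na(vals) & vals > 0)
  if (length(pos) == 0L) return(empty)
  kw_hit <- matches_keyword(tokens, keywords)
  kw_pos <- which(!is.na(kw_hit))
  keyword <- rep(NA_character_, length(pos))
  keyword_position <- rep(NA_integer_, length(pos))
  in_ctx <- rep(FALSE, length(pos))
  if (length(kw_pos) > 0L) {
    for (i in seq_along(pos)) {
      p <- pos[i]
      ok <- kw_pos[p >= kw_pos - left & p <= kw_pos + right & p != kw_pos]
      if (length(ok) > 0L) {
        in_ctx[i] <- TRUE
        nearest <- ok[order(abs(ok - p), ok)][1L]
        keyword[i] <- kw_hit[nearest]
        keyword_position[i] <- nearest
      }
    }
  }
  data.frame(position = pos, value = vals[pos], keyword = keyword,
             keyword_position = keyword_position, in_context = in_ctx,
             stringsAsFactors = FALSE)
}

#' Replace out-of-context numbers (ROOC)
#'
#' Numbers outside any keyword context window are sporadic (other labs,
#' vitals, doses) and are replaced by a magnitude tag: `"_INUM_"` for values
#' up to 1000 and `"_lgnum_"` above 1000. In-context numbers -- the lab
#' values the classifier should see -- are left untouched, as are all
#' non-number tokens. The operation is idempotent and length-preserving.
#'
#' @param tokens Character vector of tokens.
#' @param mentions Mention table from [find_numeric_mentions()] computed on
#'   `tokens`.
#' @return Character vector of the same length.
#' @examples
#' toks <- c("Cl", "93.0", "(L)", "creatinine", "5.2", "(H)")
#' rooc_transform(toks, find_numeric_mentions(toks))
#' @export
rooc_transform <- function(tokens, mentions) {
  if (nrow(mentions) == 0L) return(tokens)
  ooc <- mentions[!mentions$in_context, , drop = FALSE]
  tokens[ooc$position] <- ifelse(ooc$value > 1000, lgnum_tag, inum_tag)
  tokens
}

#' Prepare one note for modeling
#'
#' Convenience pipeline: tokenize, tag dates, and detect numeric mentions.
#'
#' @inheritParams tokenize_text
#' @inheritParams find_numeric_mentions
#' @return List with elements `tokens` (character) and `mentions`
#'   (data.frame, see [find_numeric_mentions()]).
#' @export
prep_note <- function(text, keywords = c("bun", "creatinine"),
                      left = 1L, right = 2L) {
  toks <- tag_dates(tokenize_text(text))
  list(tokens = toks,
       mentions = find_numeric_mentions(toks, keywords, left, right))
}

#' Prepare a corpus of notes
#'
#' @param notes data.frame with columns `note_id` and `text`.
#' @inheritParams find_numeric_mentions
#' @return Named list (by `note_id`) of [prep_note()] results.
#' @export
prep_corpus <- function(notes, keywords = c("bun", "creatinine"),
                        left = 1L, right = 2L) {
  stopifnot(is.data.frame(notes), all(c("note_id", "text") %in% names(notes)))
  out <- lapply(notes$text, prep_note, keywords = keywords,
                left = left, right = right)
  names(out) <- as.character(notes$note_id)
  out
}

#' Apply the mode-specific token transformation
#'
#' `basic` keeps numbers as surface tokens; `rooc`, `scalenum` and
#' `attntonum` replace out-of-context numbers with magnitude tags
#' (in-context numbers stay in the stream; for the two numeric-embedding
#' modes their surface forms are later routed around the vocabulary).
#'
#' @param prepped A [prep_note()] result.
#' @param mode One of `"basic"`, `"rooc"`, `"scalenum"`, `"attntonum"`.
#' @return Character vector of transformed tokens.
#' @export
transform_tokens <- function(prepped, mode) {
  mode <- match.arg(mode, embedding_modes())
  if (mode == "basic") prepped$tokens
  else rooc_transform(prepped$tokens, prepped$mentions)
}

#' Supported numeric-embedding modes
#' @return Character vector of mode names.
#' @export
embedding_modes <- function() c("basic", "rooc", "scalenum", "attntonum")

#' Write tokenized notes as JSON lines
#'
#' One JSON record per note with fields `note_id`, `tokens`, `mentions`.
#'
#' @param prepped Output of [prep_corpus()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tokenized <- function(prepped, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(prepped)) {
    rec <- list(note_id = id, tokens = prepped[[id]]$tokens,
                mentions = prepped[[id]]$mentions)
    writeLines(jsonlite::toJSON(rec, dataframe = "rows", auto_unbox = TRUE,
                                digits = NA), con)
  }
  invisible(path)
}
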