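#' Build a vocabulary from a training corpus
#'
#' Maps token surface forms to integer ids. Id 0 is reserved for padding and
#' ids 1-5 for the special tokens: unknown, `_date_`, `_INUM_`, `_lgnum_`,
#' and `_num_` (the placeholder id used at in-context number positions when
#' numbers are routed through the numeric-embedding path instead of the
#' lookup table). The vocabulary must be built from the training split only;
#' held-out tokens map to the unknown id at encoding time.
#'
#' Mode semantics:
#' * `basic`: numbers are ordinary vocabulary entries.
#' * `rooc`: out-of-context numbers have been replaced by tags, so only
#'   in-context number surface forms remain as entries.
#' * `scalenum` / `attntonum`: no number surface form is an entry; every
#'   in-context number is embedded from its magnitude.
#'
#' @param prepped List of [prep_note()] results (the training split only).
#' @param mode Embedding mode, see [embedding_modes()].
#' @return Object of class `nr_vocab`: list with `ids` (named integer
#'   vector over all non-pad tokens including specials), `mode`, `pad_id`
#'   (0), `unk_id`, `num_id`, and `size` (number of distinct ids including
#'   padding -- the row count of the embedding table).
#' @export
build_vocab <- function(prepped, mode = "basic") {
  mode <- match.arg(mode, embedding_modes())
  stopifnot(length(prepped) > 0L)
  specials <- c("_unk_", date_tag, inum_tag, lgnum_tag, "_num_")
  toks <- unlist(lapply(prepped, function(p) {
    tt <- transform_tokens(p, mode)
    if (mode %in% c("scalenum", "attntonum")) {
      mn <- p$mentions
      drop_pos <- mn$position[mn$in_context]
      if (length(drop_pos) > 0L) tt <- tt[-drop_pos]
    }
    tt
  }), use.names = FALSE)
  entries <- setdiff(unique(toks), specials)
  all_tokens <- c(specials, sort(entries))
  ids <- seq_along(all_tokens)
  names(ids) <- all_tokens
  structure(list(ids = ids, mode = mode, pad_id = 0L, unk_id = ids[["_unk_"]],
                 num_id = ids[["_num_"]], size = length(ids) + 1L),
            class = "nr_vocab")
}

#' @export
print.nr_vocab <- function(x, ...) {
  cat(sprintf("<nr_vocab> mode=%s, %d ids (incl. padding), embed rows %d\n",
              x$mode, x$size, x$size))
  invisible(x)
}

#' Encode a token sequence as fixed-length integer ids
#'
#' Tokens are mapped through the vocabulary (unknown tokens to the unknown
#' id), truncated at `max_len`, and right-padded with the padding id 0. For
#' the `scalenum` / `attntonum` modes, in-context number positions are
#' encoded as the `_num_` placeholder id; their embedding rows are
#' overridden by the numeric path in [embed_sequence()].
#'
#' @param prepped A [prep_note()] result.
#' @param vocab An `nr_vocab`.
#' @param max_len Output length (default 3000, the note length cutoff).
#' @return Integer vector of length exactly `max_len`.
#' @export
encode_tokens <- function(prepped, vocab, max_len = 3000L) {
  stopifnot(inherits(vocab, "nr_vocab"), max_len >= 1L)
  toks <- transform_tokens(prepped, vocab$mode)
  ids <- unname(vocab$ids[toks])
  ids[is.na(ids)] <- vocab$unk_id
  if (vocab$mode %in% c("scalenum", "attntonum")) {
    mn <- prepped$mentions
    pos <- mn$position[mn$in_context]
    pos <- pos[pos <= length(ids)]
    ids[pos] <- vocab$num_id
  }
  n <- length(ids)
  if (n >= max_len) ids[seq_len(max_len)]
  else c(ids, rep(0L, max_len - n))
}
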