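test_that("tokenizer keeps lab mentions, flags and decimals intact", {
  expect_identical(tokenize_text("BUN 24.0 (H)"), c("BUN", "24.0", "(H)"))
  expect_identical(tokenize_text("creatinine .7 (L)"),
                   c("creatinine", ".7", "(L)"))
  expect_identical(tokenize_text(""), character(0))
  expect_identical(tokenize_text("   "), character(0))
  # sentence punctuation splits off, number-internal periods do not
  expect_identical(tokenize_text("stable. BUN 24.0, recheck"),
                   c("stable", ".", "BUN", "24.0", ",", "recheck"))
  expect_false(any(tokenize_text("a  b\t c\nd") == ""))
})

test_that("date tagging replaces date tokens and substrings, preserving length", {
  expect_identical(tag_dates(c("creatinine", "5.2", "(H)", "03/05/18")),
                   c("creatinine", "5.2", "(H)", "_date_"))
  expect_identical(tag_dates(c("BUN", "24.0")), c("BUN", "24.0"))
  expect_identical(tag_dates(c("01/02/2020", "x", "03/04/18")),
                   c("_date_", "x", "_date_"))
  # hyphen-fused dates keep their fused token shape
  expect_identical(tag_dates("03/04/18-BUN"), "_date_-BUN")
  toks <- tokenize_text("seen 03/04/18 BUN 24.0 (H) f/u 1/2/19")
  expect_length(tag_dates(toks), length(toks))
})

test_that("numeric mentions respect the keyword context window", {
  m <- find_numeric_mentions(c("creatinine", "5.2", "(H)"))
  expect_equal(m$position, 2L)
  expect_equal(m$value, 5.2)
  expect_equal(m$keyword, "creatinine")
  expect_true(m$in_context)

  m <- find_numeric_mentions(c("Cl", "93.0", "(L)"))
  expect_equal(m$value, 93)
  expect_false(m$in_context)
  expect_true(is.na(m$keyword))

  expect_equal(nrow(find_numeric_mentions(character(0))), 0L)
  # left-of-keyword context and case-insensitive, hyphen-tolerant matching
  m <- find_numeric_mentions(c("24.0", "bun"))
  expect_true(m$in_context)
  m <- find_numeric_mentions(c("_date_-bun", "24.0"))
  expect_true(m$in_context)
  # pseudo-numbers and the keyword position itself are not mentions
  expect_equal(nrow(find_numeric_mentions(c("BUN", "1.2.3"))), 0L)
})

test_that("in-context flag matches a brute-force window scan", {
  set.seed(101)
  for (rep in 1:25) {
    toks <- random_tokens(sample(5:40, 1))
    m <- find_numeric_mentions(toks)
    for (i in seq_len(nrow(m))) {
      expect_identical(m$in_context[i], brute_in_context(toks, m$position[i]),
                       info = paste(toks, collapse = " "))
    }
  }
})

test_that("ROOC replaces out-of-context numbers by magnitude and is idempotent", {
  toks <- c("Cl", "93.0", "(L)")
  out <- rooc_transform(toks, find_numeric_mentions(toks))
  expect_identical(out, c("Cl", "_INUM_", "(L)"))

  toks <- c("heart", "rate", "1500.0")
  out <- rooc_transform(toks, find_numeric_mentions(toks))
  expect_identical(out, c("heart", "rate", "_lgnum_"))

  toks <- c("creatinine", "5.2", "(H)")
  expect_identical(rooc_transform(toks, find_numeric_mentions(toks)), toks)

  # exactly 1000 goes to the small-number tag
  toks <- c("dose", "1000")
  out <- rooc_transform(toks, find_numeric_mentions(toks))
  expect_identical(out, c("dose", "_INUM_"))

  set.seed(7)
  for (rep in 1:10) {
    toks <- tag_dates(random_tokens(sample(5:50, 1)))
    once <- rooc_transform(toks, find_numeric_mentions(toks))
    twice <- rooc_transform(once, find_numeric_mentions(once))
    expect_identical(once, twice)
    expect_length(once, length(toks))
  }
})

test_that("vocabulary modes include or exclude number surface forms", {
  pp <- fixture_prepped()
  vb <- build_vocab(pp, "basic")
  vr <- build_vocab(pp, "rooc")
  vs <- build_vocab(pp, "scalenum")
  # basic keeps every number token, including out-of-context ones
  expect_true("93.0" %in% names(vb$ids))
  expect_true("24.0" %in% names(vb$ids))
  # rooc drops out-of-context numbers but keeps in-context ones
  expect_false("93.0" %in% names(vr$ids))
  expect_true("_INUM_" %in% names(vr$ids))
  expect_true("24.0" %in% names(vr$ids))
  # scalenum routes every number around the table
  expect_false(any(c("93.0", "24.0", ".7", "2.5") %in% names(vs$ids)))
  expect_lt(vs$size, vr$size)
  expect_lt(vr$size, vb$size)
  # id 0 reserved for padding; ids bijective
  expect_false(0L %in% vb$ids)
  expect_false(any(duplicated(vb$ids)))
})

test_that("encoding pads, truncates and maps unknown tokens", {
  pp <- fixture_prepped()
  v <- build_vocab(pp, "basic")
  ids <- encode_tokens(pp[[1]], v, max_len = 3000L)
  expect_length(ids, 3000L)
  n <- length(pp[[1]]$tokens)
  expect_true(all(ids[(n + 1):3000] == 0L))
  expect_true(all(ids[1:n] > 0L))
  # truncation
  expect_length(encode_tokens(pp[[1]], v, max_len = 3L), 3L)
  # unseen tokens at inference map to the unknown id
  novel <- prep_note("zzzunseen token BUN 19.0 (L)")
  ids2 <- encode_tokens(novel, v, max_len = 10L)
  expect_equal(ids2[1], v$unk_id)
  # scalenum encoding puts the placeholder id at in-context numbers
  vs <- build_vocab(pp, "scalenum")
  ids3 <- encode_tokens(pp[[1]], vs, max_len = 10L)
  pos <- pp[[1]]$mentions$position[pp[[1]]$mentions$in_context]
  expect_true(all(ids3[pos] == vs$num_id))
})

test_that("tokenized notes serialize to JSON lines with mentions", {
  pp <- fixture_prepped()
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_tokenized(pp, path)
  lines <- readLines(path)
  expect_length(lines, length(pp))
  rec <- jsonlite::fromJSON(lines[1])
  expect_identical(rec$note_id, names(pp)[1])
  expect_identical(rec$tokens, pp[[1]]$tokens)
  expect_equal(rec$mentions$value, pp[[1]]$mentions$value)
})
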