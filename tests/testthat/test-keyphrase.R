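# Key-phrase extraction: preprocessing, candidates vs a brute-force
# oracle, both scorers, fuzzy de-duplication, merge-and-order.

# ---- independent oracles ----------------------------------------------

# Brute-force candidate enumeration: split on sentence enders, split on
# spaces, enumerate all n-grams, filter stopword ends.
oracle_candidates <- function(text, max_ngram = 3,
                              stops = stopword_list()) {
  out <- character(0)
  for (sent in strsplit(text, "[.!?\n]+")[[1]]) {
    toks <- strsplit(sent, " +")[[1]]
    toks <- toks[nzchar(toks)]
    for (g in seq_len(max_ngram)) {
      if (g > length(toks)) next
      for (s in seq_len(length(toks) - g + 1)) {
        w <- toks[s:(s + g - 1)]
        if (w[1] %in% stops || w[length(w)] %in% stops) next
        out <- c(out, paste(w, collapse = " "))
      }
    }
  }
  out
}

oracle_levenshtein <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  d <- matrix(0, length(ca) + 1, length(cb) + 1)
  d[, 1] <- 0:length(ca); d[1, ] <- 0:length(cb)
  for (i in seq_along(ca)) {
    for (j in seq_along(cb)) {
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1, d[i + 1, j] + 1,
                             d[i, j] + (ca[i] != cb[j]))
    }
  }
  d[length(ca) + 1, length(cb) + 1]
}

# Matching-blocks ratio by direct recursion (independent of the C++).
oracle_block_ratio <- function(a, b) {
  longest <- function(x, y) {
    best <- c(0, 0, 0)
    for (i in seq_len(nchar(x))) {
      for (j in seq_len(nchar(y))) {
        l <- 0
        while (i + l <= nchar(x) && j + l <= nchar(y) &&
               substr(x, i + l, i + l) == substr(y, j + l, j + l)) {
          l <- l + 1
        }
        if (l > best[3]) best <- c(i, j, l)
      }
    }
    best
  }
  rec <- function(x, y) {
    if (nchar(x) == 0 || nchar(y) == 0) return(0)
    m <- longest(x, y)
    if (m[3] == 0) return(0)
    m[3] +
      rec(substr(x, 1, m[1] - 1), substr(y, 1, m[2] - 1)) +
      rec(substr(x, m[1] + m[3], nchar(x)), substr(y, m[2] + m[3], nchar(y)))
  }
  tot <- nchar(a) + nchar(b)
  if (tot == 0) return(1)
  2 * rec(a, b) / tot
}

# ---- preprocessing -----------------------------------------------------

test_that("preprocessing lowercases, drops numerics and is idempotent", {
  expect_equal(preprocess_note("Pt admitted 2019 with CHF"),
               "pt admitted with chf")
  expect_equal(preprocess_note(""), "")
  expect_equal(preprocess_note("BP 120/80 recorded 10:30"), "bp recorded")
  txts <- c("Acute, renal -- failure! Seen 3x today.",
            "line one\nline two 42")
  for (tx in txts) {
    once <- preprocess_note(tx)
    expect_equal(preprocess_note(once), once)
  }
})

# ---- candidates --------------------------------------------------------

test_that("candidate n-grams match brute-force enumeration", {
  u <- tiny_universe()
  corp <- tiny_corpus(u, n_notes = 5)
  for (i in 1:5) {
    pre <- preprocess_note(corp$text[i])
    got <- extract_candidates(pre)
    want <- oracle_candidates(pre)
    expect_setequal(got$phrase, unique(want))
    tf_want <- table(want)
    expect_equal(got$term_freq[match(names(tf_want), got$phrase)],
                 as.integer(tf_want))
    # first offsets agree with naive substring search on space-padded text
    for (j in sample(nrow(got), min(20, nrow(got)))) {
      naive <- regexpr(paste0(" ", got$phrase[j]),
                       paste0(" ", pre), fixed = TRUE)[1]
      expect_equal(got$first_offset[j], as.integer(naive),
                   label = got$phrase[j])
    }
  }
  expect_equal(nrow(extract_candidates("")), 0)
})

test_that("a simple trigram yields itself plus sub-n-grams", {
  got <- extract_candidates("acute renal failure")$phrase
  expect_setequal(got, c("acute", "renal", "failure", "acute renal",
                         "renal failure", "acute renal failure"))
})

# ---- scorers -----------------------------------------------------------

test_that("frequency-position scoring follows the stated formula", {
  text <- "acute renal failure. acute pain noted. swelling noted."
  cand <- extract_candidates(text)
  stats <- doc_stats(text)
  cfg <- extractor_config()
  ranked <- score_frequency_position(cand, stats, cfg)
  # direct evaluation of the formula for a spot-checked phrase
  row <- cand[cand$phrase == "acute", ]
  want <- row$term_freq * 1 / (1 + row$first_offset / stats$doc_length)
  expect_equal(ranked$score[ranked$phrase == "acute"], want)
  bi <- cand[cand$phrase == "acute renal", ]
  want_bi <- bi$term_freq * 2 / (1 + bi$first_offset / stats$doc_length)
  expect_equal(ranked$score[ranked$phrase == "acute renal"], want_bi)
  expect_identical(ranked$rank, seq_len(nrow(ranked)))
  expect_true(all(diff(ranked$score) <= 0))
})

test_that("matched bigram scores exactly twice the matched unigram", {
  # construct candidates directly to pin offsets
  cand <- data.frame(phrase = c("alpha", "alpha beta"),
                     n_tokens = c(1L, 2L), term_freq = c(2L, 2L),
                     first_offset = c(10L, 10L))
  cand$sentence_ids <- list(1L, 1L)
  stats <- list(doc_length = 100, n_sentences = 2,
                terms = data.frame(term = c("alpha", "beta"),
                                   tf = c(2L, 2L), first_offset = c(10L, 16L),
                                   n_sent = c(1L, 1L)))
  r <- score_frequency_position(cand, stats, extractor_config())
  s_uni <- r$score[r$phrase == "alpha"]
  s_bi <- r$score[r$phrase == "alpha beta"]
  expect_equal(s_bi, 2 * s_uni)
  expect_lt(r$rank[r$phrase == "alpha beta"], r$rank[r$phrase == "alpha"])
})

test_that("lasf filter removes under-frequency candidates", {
  text <- "alpha beta. alpha gamma."
  cand <- extract_candidates(text)
  r <- score_frequency_position(cand, doc_stats(text),
                                extractor_config(lasf = 2))
  expect_identical(r$phrase, "alpha")   # only token seen twice
  expect_equal(r$rank, 1L)
})

test_that("multi-feature scorer favours sentence-dispersed terms", {
  # alpha and beta equally frequent at the same offset profile; alpha
  # spread over three sentences, beta packed into one
  text <- paste("alpha beta. beta beta alpha filler. alpha filler two.",
                "closing words here.")
  stats <- doc_stats(text)
  cand <- extract_candidates(text)
  r <- score_multifeature(cand, stats, extractor_config())
  expect_lt(r$rank[r$phrase == "alpha"], r$rank[r$phrase == "beta"])
  # deterministic on a fixed input
  expect_identical(r, score_multifeature(cand, stats, extractor_config()))
})

# ---- de-duplication ----------------------------------------------------

test_that("similarity ratios agree with independent oracles", {
  pairs <- list(c("congestive heart failure", "heart failure"),
                c("acute renal", "renal failure"),
                c("abc", "xyz"), c("same", "same"))
  for (p in pairs) {
    tot <- nchar(p[1]) + nchar(p[2])
    want_edit <- (tot - oracle_levenshtein(p[1], p[2])) / tot
    expect_equal(similarity_ratio(p[1], p[2], "edit_ratio"), want_edit,
                 tolerance = 1e-12, label = paste(p, collapse = " vs "))
    expect_equal(similarity_ratio(p[1], p[2], "block_ratio"),
                 oracle_block_ratio(p[1], p[2]),
                 tolerance = 1e-12, label = paste(p, collapse = " vs "))
  }
})

test_that("dedup drops by threshold comparison exactly as the oracle", {
  ph <- data.frame(phrase = c("congestive heart failure", "heart failure",
                              "renal cyst"),
                   score = c(3, 2, 1), rank = 1:3,
                   first_offset = c(1L, 20L, 40L))
  ratio <- similarity_ratio("congestive heart failure", "heart failure",
                            "edit_ratio")
  kept <- dedup_phrases(ph, "edit_ratio", threshold = 0.70)$phrase
  if (ratio >= 0.70) {
    expect_setequal(kept, c("congestive heart failure", "renal cyst"))
  } else {
    expect_setequal(kept, ph$phrase)
  }
  # exact duplicates collapse; disjoint strings survive
  dup <- data.frame(phrase = c("apple pie", "apple pie", "zebra"),
                    score = 3:1, rank = 1:3, first_offset = c(1L, 5L, 9L))
  expect_identical(dedup_phrases(dup, "block_ratio", 0.70)$phrase,
                   c("apple pie", "zebra"))
  # idempotent and order-stable
  once <- dedup_phrases(ph, "edit_ratio", 0.70)
  expect_identical(dedup_phrases(once, "edit_ratio", 0.70), once)
})

# ---- merge and order ---------------------------------------------------

test_that("merge keeps disjoint lists whole and orders by appearance", {
  text <- paste("quaver nimbus. corvid lumen. fjord glyph. plinth vortex.",
                "zephyr crag. bramble tarn. mesa drift. cairn sluice.",
                "dune loch. grotto spume.")
  mk <- function(phr, off) data.frame(phrase = phr, score = rev(seq_along(phr)),
                                      rank = seq_along(phr),
                                      first_offset = off)
  a <- mk(c("quaver nimbus", "corvid lumen", "fjord glyph", "plinth vortex",
            "zephyr crag"), c(1L, 16L, 30L, 43L, 58L))
  b <- mk(c("bramble tarn", "mesa drift", "cairn sluice", "dune loch",
            "grotto spume"), c(70L, 84L, 96L, 110L, 120L))
  got <- merge_and_order(a, b, text, top_n = 10)
  expect_equal(nrow(got), 10)
  expect_true(all(diff(got$first_offset) >= 0))
  # offsets re-anchored to actual positions in the note
  for (i in seq_len(nrow(got))) {
    expect_equal(got$first_offset[i],
                 as.integer(regexpr(got$phrase[i], text, fixed = TRUE)))
  }
})

test_that("merge equals a brute-force union + dedup on overlapping lists", {
  u <- tiny_universe()
  corp <- tiny_corpus(u, n_notes = 2, seed = 42)
  pre <- preprocess_note(corp$text[1])
  cand <- extract_candidates(pre)
  stats <- doc_stats(pre)
  cfg <- extractor_config()
  a <- score_frequency_position(cand, stats, cfg)
  b <- score_multifeature(cand, stats, cfg)
  top_n <- 12
  got <- merge_and_order(a, b, pre, top_n)

  # oracle: interleave top halves, drop ratio-or-containment duplicates,
  # order by first occurrence, truncate
  half <- ceiling(top_n / 2)
  pool_df <- rbind(cbind(a[a$rank <= half, ], src = "a"),
                   cbind(b[b$rank <= half, ], src = "b"))
  pool_df <- pool_df[order(pool_df$rank, pool_df$src), ]
  pool <- pool_df$phrase[!duplicated(pool_df$phrase)]
  kept <- character(0)
  for (p in pool) {
    dup <- FALSE
    for (q in kept) {
      tot <- nchar(p) + nchar(q)
      ratio <- (tot - oracle_levenshtein(p, q)) / tot
      contain <- grepl(paste0(" ", p, " "), paste0(" ", q, " "),
                       fixed = TRUE) ||
        grepl(paste0(" ", q, " "), paste0(" ", p, " "), fixed = TRUE)
      if (ratio >= cfg$dedup_threshold || contain) { dup <- TRUE; break }
    }
    if (!dup) kept <- c(kept, p)
  }
  off <- vapply(kept, function(p) {
    as.integer(regexpr(p, pre, fixed = TRUE))
  }, integer(1))
  want <- kept[order(off, kept)][seq_len(min(top_n, length(kept)))]
  expect_identical(got$phrase, want)
})

test_that("every extracted phrase occurs verbatim in the preprocessed note", {
  u <- tiny_universe()
  corp <- tiny_corpus(u, n_notes = 6, seed = 8)
  for (i in seq_len(nrow(corp))) {
    pre <- preprocess_note(corp$text[i])
    kp <- extract_keyphrases(corp$text[i], top_n = 20)
    expect_true(all(vapply(kp$phrase, grepl, logical(1), x = pre,
                           fixed = TRUE)))
  }
})

test_that("selection is monotone: smaller top_n is a subset of larger", {
  u <- tiny_universe()
  corp <- tiny_corpus(u, n_notes = 4, seed = 21,
                      note_length_tokens = c(60, 90))
  for (i in seq_len(nrow(corp))) {
    big <- extract_keyphrases(corp$text[i], top_n = 40)
    small <- extract_keyphrases(corp$text[i], top_n = 10)
    expect_true(all(small$phrase %in% big$phrase))
  }
})
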