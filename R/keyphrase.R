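# Unsupervised key-phrase extraction: preprocessing, candidate n-grams,
# two statistical scorers (frequency-position and multi-feature), fuzzy
# de-duplication, and the merge-and-order step that produces the prompt
# phrase sequence.

#' Key-phrase extractor configuration
#'
#' @param max_ngram maximum candidate length in tokens (default 3).
#' @param lasf least allowable seen frequency: candidates occurring fewer
#'   times are discarded by the frequency-position scorer (default 1).
#' @param dedup_threshold similarity ratio at or above which a
#'   lower-ranked phrase is dropped as a duplicate (default 0.70).
#' @param top_n number of phrases requested for the prompt (default 60,
#'   half the default corpus mean note length).
#' @param multiword_boost base `B` of the multi-word weight `B^(len-1)` in
#'   the frequency-position scorer (default 2).
#' @param stopwords character vector; candidates may not begin or end
#'   with one (default [stopword_list()]).
#' @return a list of class `extractor_config`.
#' @export
extractor_config <- function(max_ngram = 3, lasf = 1, dedup_threshold = 0.70,
                             top_n = 60, multiword_boost = 2,
                             stopwords = stopword_list()) {
  if (lasf < 1) stop("`lasf` must be >= 1")
  if (dedup_threshold <= 0 || dedup_threshold > 1) {
    stop("`dedup_threshold` must be in (0, 1]")
  }
  if (max_ngram < 1) stop("`max_ngram` must be >= 1")
  if (multiword_boost <= 1) stop("`multiword_boost` must be > 1")
  structure(list(max_ngram = as.integer(max_ngram), lasf = as.integer(lasf),
                 dedup_threshold = dedup_threshold,
                 top_n = as.integer(top_n),
                 multiword_boost = multiword_boost,
                 stopwords = stopwords),
            class = "extractor_config")
}

#' Preprocess a note for key-phrase extraction
#'
#' Lowercases everything, removes numeric tokens (tokens made of digits,
#' or digits mixed with punctuation), strips characters other than
#' letters, sentence enders (`.`, `!`, `?`) and newlines, and collapses
#' runs of spaces.  Newlines are preserved as standalone boundary tokens.
#' Idempotent.
#'
#' @param text raw note text.
#' @return the preprocessed text.
#' @export
#' @examples
#' preprocess_note("Pt admitted 2019 with CHF")
preprocess_note <- function(text) {
  x <- tolower(text)
  x <- gsub("\r\n?", "\n", x)
  x <- gsub("\n", " \n ", x, fixed = TRUE)
  toks <- strsplit(x, "[ \t]+")[[1]]
  toks <- toks[nzchar(toks)]
  # numeric tokens: digits possibly mixed with punctuation, no letters
  numeric_tok <- grepl("[0-9]", toks) & !grepl("[a-z]", toks)
  toks <- toks[!numeric_tok]
  toks <- gsub("[^a-z.!?\n]", "", toks)
  toks <- toks[nzchar(toks)]
  paste(toks, collapse = " ")
}

# Tokenize preprocessed text: character offsets (1-based), stripped word
# forms, per-token sentence ids, and a word/breaker flag.
tokenize_sentences <- function(text) {
  m <- gregexpr("[^ ]+", text)[[1]]
  if (m[1] == -1) {
    return(data.frame(token = character(0), word = character(0),
                      offset = integer(0), sentence = integer(0),
                      is_word = logical(0)))
  }
  toks <- regmatches(text, gregexpr("[^ ]+", text))[[1]]
  word <- gsub("[.!?\n]+$", "", toks)
  sent <- integer(length(toks))
  s <- 1L
  for (i in seq_along(toks)) {
    sent[i] <- s
    if (grepl("[.!?\n]$", toks[i])) s <- s + 1L
  }
  data.frame(token = toks, word = word, offset = as.integer(m),
             sentence = sent, is_word = nzchar(word),
             stringsAsFactors = FALSE)
}

#' Document statistics for the scorers
#'
#' Per-term frequency, first offset and sentence dispersion, plus global
#' document length (characters) and sentence count, computed on the
#' preprocessed text.
#'
#' @param text preprocessed note text (see [preprocess_note()]).
#' @return a list with `doc_length`, `n_sentences`, and a `terms`
#'   data.frame (`term`, `tf`, `first_offset`, `n_sent`).
#' @export
doc_stats <- function(text) {
  tk <- tokenize_sentences(text)
  tk <- tk[tk$is_word, , drop = FALSE]
  if (nrow(tk) == 0) {
    return(list(doc_length = nchar(text), n_sentences = 0L,
                terms = data.frame(term = character(0), tf = integer(0),
                                   first_offset = integer(0),
                                   n_sent = integer(0))))
  }
  sp <- split(seq_len(nrow(tk)), tk$word)
  terms <- data.frame(
    term = names(sp),
    tf = vapply(sp, length, integer(1)),
    first_offset = vapply(sp, function(ix) min(tk$offset[ix]), integer(1)),
    n_sent = vapply(sp, function(ix) length(unique(tk$sentence[ix])),
                    integer(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  list(doc_length = nchar(text),
       n_sentences = length(unique(tk$sentence)),
       terms = terms)
}

#' Extract candidate phrases from a preprocessed note
#'
#' All contiguous n-grams (1 to `max_ngram` tokens) that stay inside one
#' sentence (boundaries: `.`, `!`, `?`, newline) and neither begin nor
#' end with a stopword.  Exact term frequency, first character offset and
#' the set of sentences containing each candidate are recorded.
#'
#' @param text preprocessed note text.
#' @param config an `extractor_config`.
#' @return a data.frame with `phrase`, `n_tokens`, `term_freq`,
#'   `first_offset`, `sentence_ids` (list column).
#' @export
extract_candidates <- function(text, config = extractor_config()) {
  tk <- tokenize_sentences(text)
  tk <- tk[tk$is_word, , drop = FALSE]
  n <- nrow(tk)
  if (n == 0) {
    return(data.frame(phrase = character(0), n_tokens = integer(0),
                      term_freq = integer(0), first_offset = integer(0)))
  }
  stop_set <- config$stopwords
  phrases <- character(0); lens <- integer(0)
  offsets <- integer(0); sents <- integer(0)
  for (g in seq_len(config$max_ngram)) {
    if (g > n) break
    for (s in seq_len(n - g + 1)) {
      e <- s + g - 1L
      if (tk$sentence[s] != tk$sentence[e]) next
      if (tk$word[s] %in% stop_set || tk$word[e] %in% stop_set) next
      phrases <- c(phrases, paste(tk$word[s:e], collapse = " "))
      lens <- c(lens, g)
      offsets <- c(offsets, tk$offset[s])
      sents <- c(sents, tk$sentence[s])
    }
  }
  sp <- split(seq_along(phrases), phrases)
  out <- data.frame(
    phrase = names(sp),
    n_tokens = vapply(sp, function(ix) lens[ix[1]], integer(1)),
    term_freq = vapply(sp, length, integer(1)),
    first_offset = vapply(sp, function(ix) min(offsets[ix]), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$sentence_ids <- lapply(sp, function(ix) sort(unique(sents[ix])))
  out
}

# Shared ranking: descending score, ties by earlier first offset then
# lexicographic phrase.
rank_phrases <- function(df) {
  ord <- order(-df$score, df$first_offset, df$phrase)
  df <- df[ord, , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df[, c("phrase", "score", "rank", "first_offset")]
}

#' Frequency-position key-phrase scorer
#'
#' Scores candidates by term frequency weighted by how early the phrase
#' first appears and boosted for multi-word phrases:
#' `score = tf * 1/(1 + first_offset/doc_length) * B^(len-1)`.
#' Candidates seen fewer than `lasf` times are discarded.
#'
#' @param candidates data.frame from [extract_candidates()].
#' @param stats list from [doc_stats()].
#' @param config an `extractor_config`.
#' @return a ranked data.frame (`phrase`, `score`, `rank`, `first_offset`).
#' @export
score_frequency_position <- function(candidates, stats,
                                     config = extractor_config()) {
  df <- candidates[candidates$term_freq >= config$lasf, , drop = FALSE]
  if (nrow(df) == 0) {
    return(data.frame(phrase = character(0), score = numeric(0),
                      rank = integer(0), first_offset = integer(0)))
  }
  pos_factor <- 1 / (1 + df$first_offset / stats$doc_length)
  df$score <- df$term_freq * pos_factor *
    config$multiword_boost^(df$n_tokens - 1)
  rank_phrases(df)
}

#' Multi-feature key-phrase scorer
#'
#' A term-statistics scorer in the style of context-aware extractors:
#' each term gets a multiplicative "badness" from its position (later is
#' worse), its normalized frequency (rarer is worse) and its sentence
#' dispersion (concentrated is worse).  Phrase badness is
#' `prod(term_badness) / (term_freq * (1 + sum(term_badness)))`; the
#' exposed score is the negated badness so that larger means more
#' relevant throughout the module.
#'
#' @inheritParams score_frequency_position
#' @return a ranked data.frame (`phrase`, `score`, `rank`, `first_offset`).
#' @export
score_multifeature <- function(candidates, stats,
                               config = extractor_config()) {
  if (nrow(candidates) == 0 || nrow(stats$terms) == 0) {
    return(data.frame(phrase = character(0), score = numeric(0),
                      rank = integer(0), first_offset = integer(0)))
  }
  tstats <- stats$terms
  max_tf <- max(tstats$tf)
  badness <- (1 + tstats$first_offset / stats$doc_length) *
    (max_tf / tstats$tf) *
    (stats$n_sentences / tstats$n_sent)
  names(badness) <- tstats$term
  df <- candidates
  df$score <- vapply(seq_len(nrow(df)), function(i) {
    words <- strsplit(df$phrase[i], " ", fixed = TRUE)[[1]]
    b <- badness[words]
    -(prod(b) / (df$term_freq[i] * (1 + sum(b))))
  }, numeric(1))
  rank_phrases(df)
}

#' Similarity ratio between two phrases
#'
#' `block_ratio` is the matching-blocks ratio (recursively matched
#' longest common blocks, `2*M/(|a|+|b|)`); `edit_ratio` is the
#' Levenshtein similarity `(|a|+|b|-dist)/(|a|+|b|)`.
#'
#' @param a,b character strings.
#' @param method `"block_ratio"` or `"edit_ratio"`.
#' @return a value in `[0, 1]`.
#' @export
similarity_ratio <- function(a, b, method = c("block_ratio", "edit_ratio")) {
  method <- match.arg(method)
  if (method == "block_ratio") {
    .block_ratio_cpp(a, b)
  } else {
    tot <- nchar(a) + nchar(b)
    if (tot == 0) return(1)
    (tot - utils::adist(a, b)[1, 1]) / tot
  }
}

#' De-duplicate a ranked phrase list
#'
#' Scans phrases in rank order and drops any phrase whose similarity
#' ratio to an already-retained phrase is at or above `threshold`.
#' Retained phrases are re-ranked contiguously.  Idempotent and
#' order-stable.
#'
#' @param phrases ranked data.frame (`phrase`, `score`, `rank`,
#'   `first_offset`).
#' @param method similarity method, see [similarity_ratio()].
#' @param threshold drop threshold in `(0, 1]`.
#' @param max_keep stop scanning once this many phrases are retained
#'   (default `Inf`, i.e. scan everything); a performance knob for
#'   callers that only consume a ranking prefix.
#' @return the de-duplicated ranked data.frame.
#' @export
dedup_phrases <- function(phrases, method = c("block_ratio", "edit_ratio"),
                          threshold = 0.70, max_keep = Inf) {
  method <- match.arg(method)
  if (threshold <= 0 || threshold > 1) stop("`threshold` must be in (0, 1]")
  n <- nrow(phrases)
  if (n == 0) return(phrases)
  phrases <- phrases[order(phrases$rank), , drop = FALSE]
  keep <- logical(n)
  kept_txt <- character(0)
  for (i in seq_len(n)) {
    if (length(kept_txt) >= max_keep) break
    dup <- FALSE
    if (length(kept_txt) > 0) {
      if (method == "edit_ratio") {
        tot <- nchar(phrases$phrase[i]) + nchar(kept_txt)
        d <- utils::adist(phrases$phrase[i], kept_txt)[1, ]
        ratios <- ifelse(tot == 0, 1, (tot - d) / tot)
        dup <- any(ratios >= threshold)
      } else {
        for (t in kept_txt) {
          if (.block_ratio_cpp(phrases$phrase[i], t) >= threshold) {
            dup <- TRUE
            break
          }
        }
      }
    }
    if (!dup) {
      keep[i] <- TRUE
      kept_txt <- c(kept_txt, phrases$phrase[i])
    }
  }
  out <- phrases[keep, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Merge two extractors' phrases into the prompt sequence
#'
#' Takes the top `ceiling(top_n/2)` phrases by rank from each list,
#' unions them (scan order: the two rankings interleaved),
#' de-duplicates with the edit ratio at `dedup_threshold` plus a
#' token-level containment rule, re-anchors
#' each phrase at its first occurrence in `note_text`, sorts ascending by
#' that offset, and truncates to `top_n`.  The result is the ordered
#' phrase sequence used in the generation prompt.
#'
#' @param list_a,list_b ranked data.frames from the two scorers.
#' @param note_text the preprocessed note both lists were extracted from.
#' @param top_n requested phrase count.
#' @param dedup_threshold similarity threshold (default 0.70).
#' @return a data.frame (`phrase`, `first_offset`) ordered by offset.
#' @export
merge_and_order <- function(list_a, list_b, note_text, top_n,
                            dedup_threshold = 0.70) {
  half <- ceiling(top_n / 2)
  pick <- function(df) df[df$rank <= half, , drop = FALSE]
  pool <- rbind(cbind(pick(list_a), src = "a"),
                cbind(pick(list_b), src = "b"))
  if (nrow(pool) == 0) {
    return(data.frame(phrase = character(0), first_offset = integer(0)))
  }
  # scan order for dedup: the two rankings interleaved (a1, b1, a2, b2,
  # ...), so a smaller top_n always selects a prefix of a larger one's
  # scan and the selection is monotone in top_n
  pool <- pool[order(pool$rank, pool$src), , drop = FALSE]
  pool <- pool[!duplicated(pool$phrase), , drop = FALSE]
  pool$rank <- seq_len(nrow(pool))
  pool <- dedup_phrases(pool[, c("phrase", "score", "rank", "first_offset")],
                        method = "edit_ratio", threshold = dedup_threshold)
  # containment pass: a phrase that is a token-level sub-phrase of an
  # already-retained phrase (or vice versa) is the most literal duplicate
  # and slips past the ratio when the lengths differ a lot
  keep <- logical(nrow(pool))
  kept <- character(0)
  for (i in seq_len(nrow(pool))) {
    p <- paste0(" ", pool$phrase[i], " ")
    contained <- any(vapply(kept, function(q) {
      grepl(p, q, fixed = TRUE) || grepl(q, p, fixed = TRUE)
    }, logical(1)))
    if (!contained) {
      keep[i] <- TRUE
      kept <- c(kept, p)
    }
  }
  pool <- pool[keep, , drop = FALSE]
  off <- vapply(pool$phrase, function(p) {
    r <- regexpr(p, note_text, fixed = TRUE)
    as.integer(r[1])
  }, integer(1), USE.NAMES = FALSE)
  if (any(off < 0)) {
    stop("internal error: merged phrase not found in the note text")
  }
  pool$first_offset <- off
  pool <- pool[order(pool$first_offset, pool$phrase), , drop = FALSE]
  pool <- utils::head(pool, top_n)
  rownames(pool) <- NULL
  pool[, c("phrase", "first_offset")]
}

#' Extract the ordered prompt phrases from one note
#'
#' The full extraction stage: preprocess, build candidates, run both
#' scorers, de-duplicate each scorer's ranking (matching-blocks ratio for
#' the multi-feature scorer, edit ratio for the frequency-position
#' scorer), then merge and order by appearance.
#'
#' @param text raw note text.
#' @param config an `extractor_config`.
#' @param top_n phrase count; defaults to `config$top_n`.
#' @return a data.frame (`phrase`, `first_offset`) in order of appearance.
#' @export
#' @examples
#' extract_keyphrases("acute renal failure. chronic heart failure.",
#'                    top_n = 4)
extract_keyphrases <- function(text, config = extractor_config(),
                               top_n = config$top_n) {
  pre <- preprocess_note(text)
  cand <- extract_candidates(pre, config)
  stats <- doc_stats(pre)
  a <- score_frequency_position(cand, stats, config)
  b <- score_multifeature(cand, stats, config)
  half <- ceiling(top_n / 2)
  a <- dedup_phrases(a, method = "edit_ratio",
                     threshold = config$dedup_threshold, max_keep = half)
  b <- dedup_phrases(b, method = "block_ratio",
                     threshold = config$dedup_threshold, max_keep = half)
  merge_and_order(a, b, pre, top_n, config$dedup_threshold)
}
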