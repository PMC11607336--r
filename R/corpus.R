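# Synthetic clinical corpus generator.
#
# Stands in for a DUA-gated set of real discharge summaries: free-text
# notes with a skewed multilabel code distribution, where the only channel
# from label to text is a set of code-specific signature phrases embedded
# in idiosyncratic background filler.  Fully seeded and deterministic.

#' Build a universe of diagnosis codes with signature phrases
#'
#' Creates `n_codes` code specifications.  Prevalence weights follow a
#' Zipf profile (weight of code `j` proportional to `1/j`), mirroring the
#' skewed frequency of diagnosis codes in hospital data, where a handful
#' of codes dominate.  Each code owns `phrases_per_code` multi-token
#' signature phrases, unique across the whole universe, drawn from a
#' reserved vocabulary disjoint from the background filler.
#'
#' @param n_codes number of codes (default 50, the frequent-50 setting).
#' @param phrases_per_code signature phrases per code, between 2 and 6
#'   (default 3).
#' @param seed integer seed; the same seed reproduces the universe exactly.
#' @param phrase_tokens tokens per signature phrase (default 3).
#' @return a data.frame of class `code_universe` with columns `code`
#'   (character), `prevalence` (normalized weight), and `signature_phrases`
#'   (list column of character vectors).
#' @export
#' @examples
#' u <- build_code_universe(n_codes = 5, seed = 1)
#' u$code
build_code_universe <- function(n_codes = 50, phrases_per_code = 3,
                                seed = 1, phrase_tokens = 3) {
  if (!is.numeric(n_codes) || length(n_codes) != 1L || n_codes < 1) {
    stop("`n_codes` must be a positive count")
  }
  if (!is.numeric(phrases_per_code) || phrases_per_code < 2 ||
      phrases_per_code > 6) {
    stop("`phrases_per_code` must be between 2 and 6")
  }
  if (phrase_tokens < 2) stop("signature phrases must be multi-token")
  n_codes <- as.integer(n_codes)
  phrases_per_code <- as.integer(phrases_per_code)

  with_seed(child_seed(seed, "universe"), {
    vocab <- signature_vocabulary()
    n_phrases <- n_codes * phrases_per_code
    phrases <- character(0)
    # rejection-sample unique word combinations; collisions are rare for
    # the embedded pool (600 words) at any plausible universe size
    while (length(phrases) < n_phrases) {
      cand <- paste(sample(vocab, phrase_tokens, replace = FALSE),
                    collapse = " ")
      if (!(cand %in% phrases)) phrases <- c(phrases, cand)
    }
    w <- 1 / seq_len(n_codes)
    universe <- data.frame(
      code = sprintf("C%03d", seq_len(n_codes)),
      prevalence = w / sum(w),
      stringsAsFactors = FALSE
    )
    universe$signature_phrases <- split(
      phrases, rep(seq_len(n_codes), each = phrases_per_code))
    names(universe$signature_phrases) <- NULL
    class(universe) <- c("code_universe", "data.frame")
    universe
  })
}

#' Corpus generation configuration
#'
#' Assembles and validates the knobs of the synthetic corpus.  Defaults
#' define the package's reference desk-scale study conditions.
#'
#' @param n_notes number of notes to generate.
#' @param mean_codes_per_note target mean label-set cardinality (default 3).
#' @param note_length_tokens `(min, max)` whitespace-token length of the
#'   background text (default `c(80, 160)`).
#' @param signature_injection_rate probability that each signature phrase
#'   of an assigned code is embedded in the note (default 1).
#' @param signature_copies occurrences inserted per embedded phrase
#'   (default 2; findings in real summaries are typically restated).
#' @param phi_rate expected PHI surrogate tokens per note (default 0).
#' @param split_fractions `(train, val, test)` fractions summing to 1
#'   (default `c(0.7, 0.1, 0.2)`).
#' @param seed integer seed for the generator.
#' @param label_noise_rate probability that an assigned code is dropped
#'   from a note's text channel only, i.e. the code stays in the label set
#'   but contributes no phrases (default 0).  A fixture knob for building
#'   partially learnable corpora.
#' @return a validated list of class `corpus_config`.
#' @export
corpus_config <- function(n_notes = 200,
                          mean_codes_per_note = 3,
                          note_length_tokens = c(80, 160),
                          signature_injection_rate = 1,
                          signature_copies = 2,
                          phi_rate = 0,
                          split_fractions = c(0.7, 0.1, 0.2),
                          seed = 1,
                          label_noise_rate = 0) {
  cfg <- list(n_notes = as.integer(n_notes),
              mean_codes_per_note = mean_codes_per_note,
              note_length_tokens = as.integer(note_length_tokens),
              signature_injection_rate = signature_injection_rate,
              signature_copies = as.integer(signature_copies),
              phi_rate = phi_rate,
              split_fractions = split_fractions,
              seed = as.integer(seed),
              label_noise_rate = label_noise_rate)
  if (cfg$n_notes < 1) stop("`n_notes` must be positive")
  if (length(cfg$note_length_tokens) != 2L ||
      cfg$note_length_tokens[1] > cfg$note_length_tokens[2] ||
      cfg$note_length_tokens[1] < 1) {
    stop("`note_length_tokens` must be (min, max) with 1 <= min <= max")
  }
  if (cfg$signature_injection_rate < 0 || cfg$signature_injection_rate > 1) {
    stop("`signature_injection_rate` must be in [0, 1]")
  }
  if (cfg$phi_rate < 0) stop("`phi_rate` must be >= 0")
  if (length(cfg$split_fractions) != 3L ||
      any(cfg$split_fractions <= 0) || any(cfg$split_fractions >= 1) ||
      abs(sum(cfg$split_fractions) - 1) > 1e-8) {
    stop("`split_fractions` must be three values in (0,1) summing to 1")
  }
  if (cfg$mean_codes_per_note <= 0) {
    stop("`mean_codes_per_note` must be positive")
  }
  class(cfg) <- "corpus_config"
  cfg
}

#' Generate a synthetic clinical corpus
#'
#' Samples `n_notes` notes from a code universe.  Label sets are drawn by
#' per-code independent Bernoulli trials with prevalence-proportional
#' rates (resampled if empty, so every note has at least one code).  With
#' probability `signature_injection_rate`, each signature phrase of each
#' assigned code is embedded (as `signature_copies` contiguous
#' occurrences) at random positions in filler text drawn from the fixed
#' embedded vocabulary.  Splits are disjoint with sizes set by
#' `split_fractions`.  Deterministic given `(universe, config)`.
#'
#' @param universe a `code_universe` from [build_code_universe()].
#' @param config a `corpus_config`.
#' @return a data.frame of class `note_corpus` with columns `note_id`,
#'   `text`, `codes` (list column) and `split`.
#' @export
#' @examples
#' u <- build_code_universe(n_codes = 5, seed = 1)
#' corp <- generate_corpus(u, corpus_config(n_notes = 20, seed = 1))
#' table(corp$split)
generate_corpus <- function(universe, config) {
  if (!inherits(universe, "code_universe") || nrow(universe) == 0) {
    stop("`universe` must be a non-empty code_universe")
  }
  if (!inherits(config, "corpus_config")) {
    stop("`config` must be a corpus_config; see corpus_config()")
  }
  n <- config$n_notes
  L <- nrow(universe)

  with_seed(child_seed(config$seed, "corpus"), {
    # per-code Bernoulli rates targeting the requested mean cardinality
    rates <- pmin(config$mean_codes_per_note * universe$prevalence, 0.95)
    codes <- vector("list", n)
    for (i in seq_len(n)) {
      repeat {
        draw <- runif(L) < rates
        if (any(draw)) break
      }
      codes[[i]] <- universe$code[draw]
    }

    filler <- filler_vocabulary()
    lens <- sample(seq(config$note_length_tokens[1],
                       config$note_length_tokens[2]), n, replace = TRUE)
    texts <- character(n)
    for (i in seq_len(n)) {
      idx <- match(codes[[i]], universe$code)
      blocks <- character(0)
      for (j in idx) {
        if (runif(1) < config$label_noise_rate) next  # code left text-silent
        for (ph in universe$signature_phrases[[j]]) {
          if (runif(1) < config$signature_injection_rate) {
            blocks <- c(blocks, rep(ph, config$signature_copies))
          }
        }
      }
      texts[i] <- assemble_note_text(lens[i], blocks, filler)
    }

    splits <- assign_splits(n, config$split_fractions)
    corpus <- data.frame(
      note_id = sprintf("note_%05d", seq_len(n)),
      text = texts,
      split = splits,
      stringsAsFactors = FALSE
    )
    corpus$codes <- codes
    corpus <- corpus[, c("note_id", "text", "codes", "split")]
    class(corpus) <- c("note_corpus", "data.frame")

    if (config$phi_rate > 0) {
      corpus <- inject_phi(corpus, config$phi_rate,
                           protect = unlist(universe$signature_phrases),
                           seed = child_seed(config$seed, "phi"))
    }
    corpus
  })
}

# Build one note's text: filler tokens chunked into sentences, signature
# phrase blocks inserted whole at random sentence-internal boundaries.
assemble_note_text <- function(len_target, phrase_blocks, filler) {
  n_phrase_tokens <- sum(lengths(strsplit(phrase_blocks, " ", fixed = TRUE)))
  n_filler <- max(len_target - n_phrase_tokens, 8L)
  words <- sample(filler, n_filler, replace = TRUE)
  # sentence chunking: append "." to the last word of 6-12 word chunks
  pos <- 0L
  while (pos < n_filler) {
    step <- sample(6:12, 1)
    pos <- min(pos + step, n_filler)
    words[pos] <- paste0(words[pos], ".")
  }
  if (length(phrase_blocks) > 0) {
    at <- sample(0:n_filler, length(phrase_blocks), replace = TRUE)
    ord <- order(at)
    out <- character(0)
    prev <- 0L
    for (k in ord) {
      out <- c(out, words[seq_len(at[k])[seq_len(at[k]) > prev]],
               phrase_blocks[k])
      prev <- max(prev, at[k])
    }
    out <- c(out, words[seq_len(n_filler)[seq_len(n_filler) > prev]])
    words <- out
  }
  paste(words, collapse = " ")
}

# Disjoint split assignment with largest-remainder rounding.
assign_splits <- function(n, fractions) {
  raw <- fractions * n
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1
  }
  sample(rep(c("train", "val", "test"), counts))
}

#' PHI surrogate token pattern
#'
#' PHI surrogates use a reserved bracketed sentinel syntax (as real
#' de-identified corpora do), so scrubbing is exact and testable:
#' `[name-x]`, `[date-x]`, `[loc-x]`, `[id-x]` as single whitespace
#' tokens.
#'
#' @return a regular expression matching one PHI surrogate token.
#' @export
phi_token_pattern <- function() "^\\[(name|date|loc|id)-[a-z0-9]+\\]$"

make_phi_token <- function() {
  cat_ <- sample(c("name", "date", "loc", "id"), 1)
  val <- switch(cat_,
    name = sample(.phi_names, 1),
    date = sprintf("%02d%02d", sample(1:12, 1), sample(1:28, 1)),
    loc  = sample(.phi_places, 1),
    id   = paste0(sample(0:9, 6, replace = TRUE), collapse = ""))
  sprintf("[%s-%s]", cat_, val)
}

#' Insert PHI surrogate tokens into notes
#'
#' Inserts a Poisson(`phi_rate`)-distributed number of PHI surrogate
#' tokens per note at random token boundaries.  Original tokens are
#' preserved in order; boundaries inside any phrase listed in `protect`
#' are excluded, so protected phrases survive verbatim.
#'
#' @param notes a `note_corpus` (or any data.frame with a `text` column);
#'   a single note as a one-row data.frame works too.
#' @param phi_rate expected surrogates per note, `>= 0`.
#' @param protect character vector of phrases whose spans must not be
#'   split (typically the universe's signature phrases).
#' @param seed optional integer seed; if `NULL` the current RNG stream is
#'   used.
#' @return the notes with modified `text`.
#' @export
inject_phi <- function(notes, phi_rate, protect = character(0), seed = NULL) {
  if (phi_rate < 0) stop("`phi_rate` must be >= 0")
  if (phi_rate == 0) return(notes)
  run <- function() {
    for (i in seq_len(nrow(notes))) {
      k <- rpois(1, phi_rate)
      if (k == 0) next
      toks <- strsplit(notes$text[i], " ", fixed = TRUE)[[1]]
      allowed <- 0:length(toks)
      if (length(protect) > 0) {
        blocked <- integer(0)
        for (ph in protect) {
          pt <- strsplit(ph, " ", fixed = TRUE)[[1]]
          npt <- length(pt)
          if (npt < 2 || npt > length(toks)) next
          for (s in seq_len(length(toks) - npt + 1)) {
            # match allowing trailing sentence punctuation on tokens
            if (all(sub("\\.$", "", toks[s:(s + npt - 1)]) == pt)) {
              blocked <- c(blocked, s:(s + npt - 2))
            }
          }
        }
        allowed <- setdiff(allowed, blocked)
      }
      at <- sample(allowed, k, replace = TRUE)
      phi <- vapply(seq_len(k), function(...) make_phi_token(), character(1))
      ord <- order(at)
      out <- character(0)
      prev <- 0L
      for (j in ord) {
        sel <- seq_len(at[j])[seq_len(at[j]) > prev]
        out <- c(out, toks[sel], phi[j])
        prev <- max(prev, at[j])
      }
      out <- c(out, toks[seq_along(toks)[seq_along(toks) > prev]])
      notes$text[i] <- paste(out, collapse = " ")
    }
    notes
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Remove PHI surrogate tokens from notes
#'
#' Drops every whitespace token matching [phi_token_pattern()]; all other
#' tokens are preserved in order.  Idempotent, and an exact inverse of
#' [inject_phi()] by construction of the sentinel syntax.
#'
#' @param notes a `note_corpus` (or any data.frame with a `text` column).
#' @return the notes with PHI-free `text`.
#' @export
scrub_phi <- function(notes) {
  pat <- phi_token_pattern()
  notes$text <- vapply(notes$text, function(tx) {
    toks <- strsplit(tx, " ", fixed = TRUE)[[1]]
    paste(toks[!grepl(pat, toks)], collapse = " ")
  }, character(1), USE.NAMES = FALSE)
  notes
}

#' Validate corpus invariants
#'
#' Checks that note ids are unique, texts non-empty, every label belongs
#' to the universe, and splits take only the three canonical values.
#'
#' @param corpus a `note_corpus`.
#' @param universe the `code_universe` it was generated from.
#' @return invisibly `TRUE`; stops on violation.
#' @export
validate_corpus <- function(corpus, universe) {
  if (anyDuplicated(corpus$note_id)) stop("duplicate note ids")
  if (any(!nzchar(corpus$text))) stop("empty note text")
  if (!all(unlist(corpus$codes) %in% universe$code)) {
    stop("label outside the code universe")
  }
  if (!all(corpus$split %in% c("train", "val", "test"))) {
    stop("invalid split value")
  }
  invisible(TRUE)
}
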