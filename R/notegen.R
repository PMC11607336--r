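# Prompt construction and synthetic note generation.  The generation
# backend is a contract; the package ships a deterministic offline stub
# that embeds the prompt phrases, in order, inside seeded connective
# filler, so the whole pipeline runs without network access or
# credentials.

.prompt_templates <- list(
  v0301 = paste0("Write a description of a patient using %d words ",
                 "containing the following phrases sequentially:"),
  v0613 = paste0("Write a description of a patient using %d words. ",
                 "The description should contain the following phrases ",
                 "sequentially:")
)

#' Build a note-generation prompt
#'
#' Two instruction variants are supported, differing only in the wording
#' that precedes the comma-separated ordered phrase list.
#'
#' @param phrases character vector of ordered key phrases (non-empty).
#' @param variant `"v0301"` or `"v0613"` (default).
#' @param word_budget word count named in the instruction (default 2250).
#' @return a list of class `note_prompt` with `instruction`, `phrases`,
#'   `variant`, `word_budget`.
#' @export
#' @examples
#' p <- build_prompt(c("acute renal failure", "dialysis initiated"))
#' p$instruction
build_prompt <- function(phrases, variant = c("v0613", "v0301"),
                         word_budget = 2250) {
  variant <- match.arg(variant)
  if (length(phrases) == 0) stop("`phrases` must be non-empty")
  structure(list(
    instruction = sprintf(.prompt_templates[[variant]], word_budget),
    phrases = as.character(phrases),
    variant = variant,
    word_budget = as.integer(word_budget)
  ), class = "note_prompt")
}

#' @export
format.note_prompt <- function(x, ...) {
  paste(x$instruction, paste(x$phrases, collapse = ", "))
}

#' @export
print.note_prompt <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

# Connective vocabulary kept disjoint from the synthetic corpus's filler
# word list, so stub sentences never accidentally pre-empt a phrase's
# first occurrence.
.stub_openers <- c(
  "the writeup mentions", "records indicate", "caregivers documented",
  "the summary describes", "charting shows", "observers recorded",
  "the entry lists", "staff reported"
)
.stub_tails <- c(
  "per the chart", "as recorded", "in this episode", "by the team",
  "on reassessment", "at that point", "per documentation", "as summarized"
)

#' Deterministic offline note generation
#'
#' Produces a note that embeds every prompt phrase verbatim, in prompt
#' order, inside templated connective sentences.  The seed controls only
#' the connective filler (synonym choice), never the phrase tokens, so
#' different seeds paraphrase the surroundings while the phrase
#' subsequence is identical.  Output is truncated to
#' `max_completion_tokens` whitespace tokens if necessary.
#'
#' @param prompt a `note_prompt`.
#' @param seed integer seed.
#' @param max_completion_tokens output token budget (default 3000).
#' @return the generated note text.
#' @export
stub_generate <- function(prompt, seed = 0, max_completion_tokens = 3000) {
  stopifnot(inherits(prompt, "note_prompt"))
  with_seed(child_seed(seed, "stub"), {
    n <- length(prompt$phrases)
    op <- sample(.stub_openers, n, replace = TRUE)
    tl <- sample(.stub_tails, n, replace = TRUE)
    sentences <- paste0(op, " ", prompt$phrases, " ", tl, ".")
    text <- paste(sentences, collapse = " ")
    toks <- strsplit(text, " ", fixed = TRUE)[[1]]
    if (length(toks) > max_completion_tokens) {
      # shed connective tails first, then hard-truncate
      sentences <- paste0(op, " ", prompt$phrases, ".")
      text <- paste(sentences, collapse = " ")
      toks <- strsplit(text, " ", fixed = TRUE)[[1]]
      if (length(toks) > max_completion_tokens) {
        toks <- toks[seq_len(max_completion_tokens)]
        text <- paste(toks, collapse = " ")
      }
    }
    text
  })
}

#' The deterministic stub generation backend
#'
#' A `generation_backend` object wrapping [stub_generate()].  Backends
#' are lists with an `id`, a `deterministic` capability flag, and a
#' `generate(prompt, max_completion_tokens, seed)` function whose output
#' never exceeds the token budget.
#'
#' @return a `generation_backend`.
#' @export
stub_backend <- function() {
  structure(list(
    id = "stub",
    deterministic = TRUE,
    generate = function(prompt, max_completion_tokens = 3000, seed = 0) {
      stub_generate(prompt, seed = seed,
                    max_completion_tokens = max_completion_tokens)
    }
  ), class = "generation_backend")
}

#' Generate one synthetic note through a backend
#'
#' Calls the backend, retrying on failure up to `retries` times and then
#' falling back to the stub (the fallback is flagged in the attached
#' log).  The returned text carries a `generation_log` attribute with the
#' backend id, prompt/output token counts, and the fallback flag.
#'
#' @param backend a `generation_backend`.
#' @param prompt a `note_prompt`.
#' @param max_completion_tokens output token budget (default 3000).
#' @param seed integer seed forwarded to the backend.
#' @param retries attempts before falling back to the stub (default 2).
#' @return the generated text with a `generation_log` attribute.
#' @export
generate_note <- function(backend, prompt, max_completion_tokens = 3000,
                          seed = 0, retries = 2) {
  stopifnot(inherits(backend, "generation_backend"),
            inherits(prompt, "note_prompt"))
  text <- NULL
  fallback <- FALSE
  last_err <- NULL
  for (i in seq_len(retries + 1)) {
    text <- tryCatch(
      backend$generate(prompt, max_completion_tokens, seed),
      error = function(e) {
        last_err <<- conditionMessage(e)
        NULL
      })
    if (!is.null(text) && nzchar(text)) break
  }
  if (is.null(text) || !nzchar(text)) {
    text <- stub_generate(prompt, seed = seed,
                          max_completion_tokens = max_completion_tokens)
    fallback <- TRUE
  }
  n_out <- length(strsplit(text, "[ \n]+")[[1]])
  if (n_out > max_completion_tokens) {
    stop(sprintf("backend '%s' exceeded the completion budget (%d > %d)",
                 backend$id, n_out, max_completion_tokens))
  }
  attr(text, "generation_log") <- list(
    backend = backend$id,
    prompt_tokens = length(strsplit(format(prompt), " ")[[1]]),
    output_tokens = n_out,
    fallback = fallback,
    error = last_err
  )
  text
}

#' Phrase coverage of a generated note
#'
#' `present_fraction` is the share of phrases found verbatim in the
#' text; `in_order_fraction` is the length of the longest increasing
#' subsequence of first-match offsets (taken in prompt-phrase order)
#' divided by the number of phrases.
#'
#' @param text generated note text.
#' @param phrases character vector of prompt phrases.
#' @return named numeric vector `c(present_fraction, in_order_fraction)`.
#' @export
#' @examples
#' phrase_coverage("b then a", c("a", "b"))
phrase_coverage <- function(text, phrases) {
  n <- length(phrases)
  if (n == 0) {
    return(c(present_fraction = 1, in_order_fraction = 1))
  }
  off <- vapply(phrases, function(p) {
    as.integer(regexpr(p, text, fixed = TRUE)[1])
  }, integer(1), USE.NAMES = FALSE)
  present <- off > 0
  seq_off <- off[present]
  lis <- 0L
  if (length(seq_off) > 0) {
    # O(n^2) longest strictly increasing subsequence
    dp <- rep(1L, length(seq_off))
    for (i in seq_along(seq_off)) {
      for (j in seq_len(i - 1L)) {
        if (seq_off[j] < seq_off[i] && dp[j] + 1L > dp[i]) dp[i] <- dp[j] + 1L
      }
    }
    lis <- max(dp)
  }
  c(present_fraction = sum(present) / n, in_order_fraction = lis / n)
}

#' Replace a corpus's text with synthetic notes
#'
#' For every note: extract the ordered key phrases, build the prompt,
#' and generate a synthetic note through the backend.  Note ids, label
#' sets and split assignments are preserved — only the text changes — so
#' utility evaluation against the original test labels stays
#' well-defined.
#'
#' @param notes a `note_corpus`.
#' @param config an `extractor_config` controlling phrase extraction.
#' @param backend a `generation_backend` (default the stub).
#' @param variant prompt variant (default `"v0613"`).
#' @param top_n phrases per prompt (default `config$top_n`).
#' @param seed integer master seed; each note's generation seed derives
#'   from it and the note id.
#' @param max_completion_tokens per-note output budget (default 3000).
#' @return a `note_corpus` with synthetic `text`.
#' @export
synthesize_corpus <- function(notes, config = extractor_config(),
                              backend = stub_backend(),
                              variant = "v0613", top_n = config$top_n,
                              seed = 1, max_completion_tokens = 3000) {
  out <- notes
  for (i in seq_len(nrow(notes))) {
    kp <- extract_keyphrases(notes$text[i], config, top_n = top_n)
    if (nrow(kp) == 0) {
      # pathological note with no extractable phrase: keep a minimal stub
      out$text[i] <- "no salient findings documented."
      next
    }
    prompt <- build_prompt(kp$phrase, variant = variant)
    out$text[i] <- as.character(generate_note(
      backend, prompt, max_completion_tokens = max_completion_tokens,
      seed = child_seed(seed, notes$note_id[i])))
  }
  out
}
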