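# Readers and writers: JSON-lines corpora, tab-delimited prediction
# matrices, and YAML run configuration.  All serialization is
# deterministic (stable key order, fixed numeric formatting) so identical
# inputs produce byte-identical files.

#' Write notes as JSON-lines
#'
#' One JSON object per line with keys `note_id`, `text`, `codes`, `split`
#' in that fixed order; UTF-8.  Lossless against [read_notes()].
#'
#' @param notes a `note_corpus` data.frame.
#' @param path output file path.
#' @return invisibly `path`.
#' @export
write_notes <- function(notes, path) {
  if (anyDuplicated(notes$note_id)) stop("duplicate note ids")
  lines <- vapply(seq_len(nrow(notes)), function(i) {
    jsonlite::toJSON(list(
      note_id = jsonlite::unbox(notes$note_id[i]),
      text = jsonlite::unbox(notes$text[i]),
      codes = as.character(notes$codes[[i]]),
      split = jsonlite::unbox(notes$split[i])
    ))
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' Read a JSON-lines note file
#'
#' @param path file written by [write_notes()] (or any JSON-lines file
#'   with the same keys).
#' @return a `note_corpus` data.frame; an empty file yields zero rows.
#' @export
read_notes <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  n <- length(lines)
  out <- data.frame(note_id = character(n), text = character(n),
                    split = character(n), stringsAsFactors = FALSE)
  codes <- vector("list", n)
  for (i in seq_len(n)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
                    error = function(e) {
                      stop(sprintf("malformed JSON on line %d of %s: %s",
                                   i, path, conditionMessage(e)),
                           call. = FALSE)
                    })
    need <- c("note_id", "text", "codes", "split")
    if (!all(need %in% names(rec))) {
      stop(sprintf("line %d of %s is missing required keys", i, path),
           call. = FALSE)
    }
    out$note_id[i] <- rec$note_id
    out$text[i] <- rec$text
    out$split[i] <- rec$split
    codes[[i]] <- as.character(rec$codes)
  }
  out$codes <- codes
  out <- out[, c("note_id", "text", "codes", "split")]
  if (anyDuplicated(out$note_id)) {
    stop(sprintf("duplicate note_id in %s", path), call. = FALSE)
  }
  class(out) <- c("note_corpus", "data.frame")
  out
}

#' Write a prediction-probability matrix
#'
#' Tab-delimited text: header row `note_id` followed by the label codes;
#' one row per note.  Values are printed with 17 significant digits so a
#' round-trip preserves them to better than 12 significant digits.
#'
#' @param note_ids character vector of row identifiers.
#' @param probabilities numeric matrix `length(note_ids) x L` in `[0, 1]`
#'   with column names set to the label codes.
#' @param path output file path.
#' @return invisibly `path`.
#' @export
write_prediction_matrix <- function(note_ids, probabilities, path) {
  probabilities <- as.matrix(probabilities)
  if (length(note_ids) != nrow(probabilities)) {
    stop("`note_ids` length must equal the number of rows")
  }
  if (nrow(probabilities) > 0 &&
      (anyNA(probabilities) || min(probabilities) < 0 ||
       max(probabilities) > 1)) {
    stop("probabilities must lie in [0, 1]")
  }
  if (is.null(colnames(probabilities))) {
    stop("`probabilities` must carry label codes as column names")
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("note_id", colnames(probabilities)), collapse = "\t"),
             con, useBytes = TRUE)
  for (i in seq_len(nrow(probabilities))) {
    writeLines(paste(c(note_ids[i],
                       sprintf("%.17g", probabilities[i, ])),
                     collapse = "\t"), con, useBytes = TRUE)
  }
  invisible(path)
}

#' Read a prediction-probability matrix
#'
#' @param path file written by [write_prediction_matrix()].
#' @return a numeric matrix with `note_id` rownames and label-code
#'   colnames; a header-only file yields a `0 x L` matrix.
#' @export
read_prediction_matrix <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) == 0) stop(sprintf("%s is empty (no header)", path))
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  labels <- header[-1]
  body <- lines[-1]
  mat <- matrix(numeric(0), nrow = 0, ncol = length(labels),
                dimnames = list(NULL, labels))
  if (length(body) > 0) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    widths <- lengths(parts)
    if (any(widths != length(header))) {
      bad <- which(widths != length(header))[1]
      stop(sprintf("ragged row at line %d of %s", bad + 1L, path),
           call. = FALSE)
    }
    ids <- vapply(parts, `[[`, character(1), 1)
    vals <- t(vapply(parts, function(p) as.numeric(p[-1]),
                     numeric(length(labels))))
    if (length(labels) == 1L) vals <- matrix(vals, ncol = 1)
    if (anyNA(vals)) stop(sprintf("non-numeric value in %s", path))
    if (nrow(vals) > 0 && (min(vals) < 0 || max(vals) > 1)) {
      stop(sprintf("probability outside [0, 1] in %s", path))
    }
    mat <- vals
    dimnames(mat) <- list(ids, labels)
  }
  mat
}

#' Default run configuration
#'
#' The fully resolved default configuration: one section per pipeline
#' stage plus the global `seed` that all child seeds derive from.
#'
#' @return a nested list of class `run_config`.
#' @export
default_config <- function() {
  cfg <- list(
    seed = 1L,
    corpus = unclass(corpus_config()),
    keyphrase = unclass(extractor_config()),
    notegen = list(variant = "v0613", word_budget = 2250L,
                   max_completion_tokens = 3000L, backend = "stub"),
    classifier = unclass(classifier_config()),
    attack = unclass(attack_config()),
    sweep = list(training_set_sizes = c(800L, 600L, 400L),
                 max_note_tokens = c(256L, 128L, 64L),
                 key_phrase_counts = c(60L, 30L, 15L),
                 n_seed_replicates = 3L)
  )
  cfg$corpus$seed <- NULL  # stage seeds derive from the global seed
  cfg$classifier$seed <- NULL
  cfg$attack$seed <- NULL
  class(cfg) <- "run_config"
  cfg
}

#' Load a run configuration file
#'
#' Reads a YAML file, validates every key against the defaults (unknown
#' keys are rejected by name), and overlays the file's values on the
#' defaults.  An empty file yields all defaults.
#'
#' @param path YAML file path.
#' @param quiet suppress the echo of the resolved configuration.
#' @return a fully resolved `run_config`.
#' @export
load_config <- function(path, quiet = FALSE) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  if (!is.null(user)) {
    if (!is.list(user)) stop("config file must be a YAML mapping")
    bad <- setdiff(names(user), names(cfg))
    if (length(bad) > 0) {
      stop(sprintf("unknown config section(s): %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    for (sec in names(user)) {
      if (sec == "seed") {
        cfg$seed <- as.integer(user$seed)
        next
      }
      bad <- setdiff(names(user[[sec]]), names(cfg[[sec]]))
      if (length(bad) > 0) {
        stop(sprintf("unknown key(s) in section '%s': %s", sec,
                     paste(bad, collapse = ", ")), call. = FALSE)
      }
      cfg[[sec]] <- modifyList(cfg[[sec]], user[[sec]])
    }
  }
  if (!quiet) {
    message("resolved config: ",
            jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE))
  }
  cfg
}
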