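# The victim/utility model: a bidirectional-LSTM encoder with a
# per-label attention head and one binary sigmoid output per code.
# Training runs in compiled code (src/laat.cpp); this file holds the
# configuration, vocabulary, vectorization, and the user-facing train /
# predict / serialize surface.

#' Classifier configuration
#'
#' Desk-scale defaults are deliberately small so the full pipeline runs
#' on one CPU; every dimension is configurable.
#'
#' @param vocab_size vocabulary cap; most frequent training tokens kept
#'   (default 8000).
#' @param embedding_dim token embedding width (default 32).
#' @param recurrent_hidden_dim LSTM hidden width per direction
#'   (default 16).
#' @param attention_dim attention projection width (default 16).
#' @param max_note_tokens notes are truncated to their first this-many
#'   whitespace tokens (default 256).
#' @param epochs maximum training epochs (default 20).
#' @param batch_size minibatch size (default 16).
#' @param learning_rate Adam step size (default 0.01).
#' @param decision_threshold probability threshold for F1/validation
#'   (default 0.5).
#' @param patience early-stopping patience in epochs on validation
#'   micro-F1; 0 disables early stopping (default 5).
#' @param seed integer seed for initialization and data order.
#' @return a list of class `classifier_config`.
#' @export
classifier_config <- function(vocab_size = 8000, embedding_dim = 32,
                              recurrent_hidden_dim = 16,
                              attention_dim = 16, max_note_tokens = 256,
                              epochs = 20, batch_size = 16,
                              learning_rate = 0.01,
                              decision_threshold = 0.5, patience = 5,
                              seed = 1) {
  cfg <- list(vocab_size = as.integer(vocab_size),
              embedding_dim = as.integer(embedding_dim),
              recurrent_hidden_dim = as.integer(recurrent_hidden_dim),
              attention_dim = as.integer(attention_dim),
              max_note_tokens = as.integer(max_note_tokens),
              epochs = as.integer(epochs),
              batch_size = as.integer(batch_size),
              learning_rate = learning_rate,
              decision_threshold = decision_threshold,
              patience = as.integer(patience),
              seed = as.integer(seed))
  if (any(unlist(cfg[c("vocab_size", "embedding_dim",
                       "recurrent_hidden_dim", "attention_dim",
                       "max_note_tokens", "epochs", "batch_size")]) < 1)) {
    stop("all dimensions and counts must be positive")
  }
  if (cfg$decision_threshold <= 0 || cfg$decision_threshold >= 1) {
    stop("`decision_threshold` must be in (0, 1)")
  }
  class(cfg) <- "classifier_config"
  cfg
}

# Reserved token ids.
.PAD_ID <- 1L
.UNK_ID <- 2L

#' Build a frequency-capped vocabulary
#'
#' Tokens are whitespace-delimited.  The `vocab_size` most frequent
#' tokens are kept (ties broken alphabetically); ids 1 and 2 are
#' reserved for padding and unknown tokens.
#'
#' @param texts character vector of training texts.
#' @param vocab_size cap on the number of word entries.
#' @return named integer vector mapping token to id.
#' @export
build_vocabulary <- function(texts, vocab_size = 8000) {
  toks <- unlist(strsplit(texts, "[ \n]+"))
  toks <- toks[nzchar(toks)]
  tab <- table(toks)
  ord <- order(-as.integer(tab), names(tab))
  words <- names(tab)[ord][seq_len(min(length(tab), vocab_size))]
  setNames(seq_along(words) + 2L, words)
}

#' Map a note to a token-id sequence
#'
#' Whitespace tokens mapped through the vocabulary (unknown tokens get
#' the reserved unknown id), truncated to the first `max_note_tokens`
#' tokens.  Empty text yields a single padding id.
#'
#' @param text note text.
#' @param vocabulary named id map from [build_vocabulary()].
#' @param max_note_tokens truncation cap.
#' @return integer vector of token ids (1-based).
#' @export
vectorize_note <- function(text, vocabulary, max_note_tokens) {
  toks <- strsplit(text, "[ \n]+")[[1]]
  toks <- toks[nzchar(toks)]
  if (length(toks) == 0) return(.PAD_ID)
  toks <- toks[seq_len(min(length(toks), max_note_tokens))]
  ids <- unname(vocabulary[toks])
  ids[is.na(ids)] <- .UNK_ID
  as.integer(ids)
}

# Glorot-uniform initialization of all parameter blocks, seeded.
init_params <- function(V, d, u, da, L, seed) {
  gl <- function(nr, nc) {
    lim <- sqrt(6 / (nr + nc))
    matrix(runif(nr * nc, -lim, lim), nr, nc)
  }
  with_seed(seed, {
    p <- list(
      E = gl(V, d),
      Wxf = gl(4 * u, d), Whf = gl(4 * u, u), bf = rep(0, 4 * u),
      Wxb = gl(4 * u, d), Whb = gl(4 * u, u), bb = rep(0, 4 * u),
      W = gl(da, 2 * u), U = gl(da, L),
      O = gl(L, 2 * u), bo = rep(0, L)
    )
    # forget-gate bias of 1 eases gradient flow early in training
    p$bf[(u + 1):(2 * u)] <- 1
    p$bb[(u + 1):(2 * u)] <- 1
    p
  })
}

# Label matrix (n x L, colnames = codes) from a corpus's codes column.
label_matrix <- function(notes, codes) {
  y <- matrix(0, nrow(notes), length(codes),
              dimnames = list(notes$note_id, codes))
  for (i in seq_len(nrow(notes))) {
    y[i, match(notes$codes[[i]], codes)] <- 1
  }
  y
}

#' Train the label-attention classifier
#'
#' Minimizes summed per-label binary cross-entropy with Adam; early
#' stopping (optional) tracks validation micro-F1 and restores the best
#' parameters.  Fully seeded: initialization and the per-epoch data
#' order derive from `config$seed`, so the same inputs reproduce the
#' same loss trajectory and parameters.
#'
#' @param train_notes,val_notes `note_corpus` data.frames; labels must
#'   lie inside the universe.
#' @param universe the `code_universe` defining the label space.
#' @param config a `classifier_config`.
#' @return a `laat_classifier` object: vocabulary, parameters, label
#'   codes, config and training metadata (epoch losses, validation F1
#'   trajectory, best epoch).
#' @export
train_classifier <- function(train_notes, val_notes, universe,
                             config = classifier_config()) {
  if (nrow(train_notes) == 0 || nrow(val_notes) == 0) {
    stop("train and validation sets must be non-empty")
  }
  bad <- setdiff(unlist(c(train_notes$codes, val_notes$codes)),
                 universe$code)
  if (length(bad) > 0) {
    stop(sprintf("label(s) outside the universe: %s",
                 paste(utils::head(bad, 5), collapse = ", ")))
  }
  vocab <- build_vocabulary(train_notes$text, config$vocab_size)
  docs <- lapply(train_notes$text, vectorize_note, vocabulary = vocab,
                 max_note_tokens = config$max_note_tokens)
  vdocs <- lapply(val_notes$text, vectorize_note, vocabulary = vocab,
                  max_note_tokens = config$max_note_tokens)
  y <- label_matrix(train_notes, universe$code)
  vy <- label_matrix(val_notes, universe$code)

  V <- length(vocab) + 2L
  params <- init_params(V, config$embedding_dim,
                        config$recurrent_hidden_dim, config$attention_dim,
                        nrow(universe), child_seed(config$seed, "init"))
  perms <- with_seed(child_seed(config$seed, "order"), {
    t(vapply(seq_len(config$epochs),
             function(...) sample.int(nrow(train_notes)),
             integer(nrow(train_notes))))
  })
  if (nrow(train_notes) == 1L) perms <- matrix(1L, config$epochs, 1L)

  fit <- .laat_train_cpp(params, docs, y, vdocs, vy, perms,
                         config$epochs, config$batch_size,
                         config$learning_rate, config$decision_threshold,
                         config$patience)
  structure(list(
    vocabulary = vocab,
    params = fit$params,
    codes = universe$code,
    config = config,
    meta = list(epoch_loss = fit$epoch_loss,
                epoch_val_f1 = fit$epoch_val_f1,
                best_epoch = fit$best_epoch,
                n_train = nrow(train_notes), n_val = nrow(val_notes))
  ), class = "laat_classifier")
}

#' @export
print.laat_classifier <- function(x, ...) {
  cat(sprintf(paste0("label-attention BiLSTM classifier: %d labels, ",
                     "vocab %d, trained %d epoch(s) (best %d)\n"),
              length(x$codes), length(x$vocabulary),
              length(x$meta$epoch_loss), x$meta$best_epoch))
  invisible(x)
}

#' Predict per-label probabilities
#'
#' A pure function of `(model, notes)`: row `i` holds the per-label
#' probabilities of note `i`.
#'
#' @param model a `laat_classifier`.
#' @param notes a `note_corpus` (only `text` and `note_id` are used).
#' @return numeric matrix `n x L` with note ids as rownames and label
#'   codes as colnames.
#' @export
predict_probabilities <- function(model, notes) {
  docs <- lapply(notes$text, vectorize_note, vocabulary = model$vocabulary,
                 max_note_tokens = model$config$max_note_tokens)
  out <- .laat_predict_cpp(model$params, docs)
  dimnames(out) <- list(notes$note_id, model$codes)
  out
}

#' Encoder hidden states for one note
#'
#' Runs the embedding and bidirectional LSTM only, returning the
#' concatenated hidden states — the input of [label_attention()].
#'
#' @param model a `laat_classifier`.
#' @param text one note's text.
#' @return numeric matrix `T x 2u` (tokens by hidden).
#' @export
hidden_states <- function(model, text) {
  ids <- vectorize_note(text, model$vocabulary,
                        model$config$max_note_tokens)
  .laat_hidden_cpp(model$params, ids)
}

#' Per-label attention over encoder states
#'
#' The attention head in isolation: `Z = tanh(W %*% t(H))`, per-label
#' weights `softmax_t(t(U) %*% Z)`, label vector = attention-weighted
#' sum of hidden states, logit = inner product with the label's output
#' weights plus bias.
#'
#' @param hidden_states numeric matrix `T x 2u` of encoder states.
#' @param params parameter list with `W` (`da x 2u`), `U` (`da x L`),
#'   `O` (`L x 2u`), `bo` (length L) — e.g. `model$params`.
#' @return a list: `vectors` (`L x 2u` label-specific document vectors),
#'   `weights` (`L x T` attention weights, rows sum to 1),
#'   `logits` and `probabilities` (length L).
#' @export
label_attention <- function(hidden_states, params) {
  H <- t(as.matrix(hidden_states))              # 2u x T
  if (ncol(H) == 0 || nrow(H) == 0) stop("zero-length hidden states")
  Z <- tanh(params$W %*% H)                     # da x T
  S <- t(params$U) %*% Z                        # L x T
  A <- t(apply(S, 1, function(s) {
    e <- exp(s - max(s))
    e / sum(e)
  }))
  if (ncol(H) == 1) A <- matrix(1, nrow(S), 1)  # apply() drops dims at T=1
  V <- H %*% t(A)                               # 2u x L
  logits <- as.vector(rowSums(params$O * t(V)) + as.vector(params$bo))
  list(vectors = t(V), weights = A, logits = logits,
       probabilities = 1 / (1 + exp(-logits)))
}

#' Save / load a trained classifier
#'
#' Round-trips the full model object (vocabulary, parameters, config,
#' metadata); a reloaded model reproduces predictions bit-identically.
#'
#' @param model a `laat_classifier`.
#' @param path file path.
#' @return `save_classifier` returns `path` invisibly; `load_classifier`
#'   returns the model.
#' @export
save_classifier <- function(model, path) {
  stopifnot(inherits(model, "laat_classifier"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "laat_classifier"))
  model
}
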