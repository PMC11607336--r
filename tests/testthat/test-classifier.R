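# The BiLSTM label-attention classifier: analytic gradients vs finite
# differences, vectorization, the attention head, determinism,
# serialization, learnability on the signature fixture, and the
# note-length utility trend.

test_that("analytic gradients match central finite differences", {
  p <- notemia:::init_params(V = 8, d = 3, u = 2, da = 2, L = 2, seed = 7)
  ids <- c(3L, 5L, 4L, 7L)
  y <- c(1, 0)
  lg <- notemia:::.laat_loss_grad_cpp(p, ids, y)
  eps <- 1e-6
  for (nm in names(p)) {
    g <- lg$grads[[nm]]
    num <- g
    for (i in seq_along(p[[nm]])) {
      pp <- p; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- p; pm[[nm]][i] <- pm[[nm]][i] - eps
      num[i] <- (notemia:::.laat_loss_grad_cpp(pp, ids, y)$loss -
                 notemia:::.laat_loss_grad_cpp(pm, ids, y)$loss) / (2 * eps)
    }
    expect_lt(max(abs(num - g)) / (max(abs(num)) + 1e-8), 1e-5)
  }
})

test_that("vectorization truncates, maps unknowns, and handles empties", {
  vocab <- build_vocabulary(c("a b c d e f g h i j", "a b"), 5)
  expect_length(vocab, 5)
  ids <- vectorize_note("a b c d e f g h i j", vocab, 5)
  expect_length(ids, 5)
  expect_identical(ids, unname(vocab[c("a", "b", "c", "d", "e")]))
  expect_identical(vectorize_note("zz a", vocab, 10)[1], 2L)  # unknown id
  expect_identical(vectorize_note("", vocab, 10), 1L)          # padding id
  short <- vectorize_note("a b", vocab, 100)
  expect_length(short, 2)
})

test_that("attention weights are a distribution and degenerate correctly", {
  u <- tiny_universe(n_codes = 4)
  corp <- tiny_corpus(u, n_notes = 30, seed = 12)
  sp <- notemia:::split_corpus(corp)
  m <- train_classifier(sp$train, sp$val, u,
                        classifier_config(epochs = 1, patience = 0))
  H <- hidden_states(m, corp$text[1])
  att <- label_attention(H, m$params)
  expect_equal(dim(att$vectors), c(4, 2 * m$config$recurrent_hidden_dim))
  expect_equal(unname(rowSums(att$weights)), rep(1, 4), tolerance = 1e-12)
  # single token: every label vector equals that token's hidden state
  att1 <- label_attention(H[1, , drop = FALSE], m$params)
  for (l in 1:4) expect_equal(unname(att1$vectors[l, ]), unname(H[1, ]))
  expect_error(label_attention(H[0, , drop = FALSE], m$params),
               "zero-length")
})

test_that("attention head reproduces the compiled prediction path", {
  u <- tiny_universe(n_codes = 4)
  corp <- tiny_corpus(u, n_notes = 30, seed = 12)
  sp <- notemia:::split_corpus(corp)
  m <- train_classifier(sp$train, sp$val, u,
                        classifier_config(epochs = 2, patience = 0))
  pr <- predict_probabilities(m, corp[1:5, ])
  for (i in 1:5) {
    att <- label_attention(hidden_states(m, corp$text[i]), m$params)
    expect_equal(unname(att$probabilities), unname(pr[i, ]),
                 tolerance = 1e-12)
  }
})

test_that("training is deterministic and predictions are pure", {
  u <- tiny_universe(n_codes = 4)
  corp <- tiny_corpus(u, n_notes = 40, seed = 9)
  sp <- notemia:::split_corpus(corp)
  cfg <- classifier_config(epochs = 3, patience = 0, seed = 11)
  m1 <- train_classifier(sp$train, sp$val, u, cfg)
  m2 <- train_classifier(sp$train, sp$val, u, cfg)
  expect_identical(m1$meta$epoch_loss, m2$meta$epoch_loss)
  expect_identical(m1$params, m2$params)

  pr <- predict_probabilities(m1, sp$test)
  expect_true(all(pr >= 0 & pr <= 1))
  perm <- sample(nrow(sp$test))
  pr_perm <- predict_probabilities(m1, sp$test[perm, ])
  expect_identical(unname(pr_perm), unname(pr[perm, ]))

  path <- withr::local_tempfile(fileext = ".rds")
  save_classifier(m1, path)
  m3 <- load_classifier(path)
  expect_identical(predict_probabilities(m3, sp$test), pr)
})

test_that("labels outside the universe are rejected", {
  u <- tiny_universe(n_codes = 4)
  corp <- tiny_corpus(u, n_notes = 20)
  corp$codes[[1]] <- c(corp$codes[[1]], "C999")
  sp <- notemia:::split_corpus(corp)
  expect_error(train_classifier(sp$train, sp$val, u, classifier_config()),
               "C999")
})

test_that("the fully-injected fixture is learnable to high micro-F1", {
  u <- build_code_universe(n_codes = 20, seed = 1)
  corp <- generate_corpus(u, corpus_config(
    n_notes = 300, seed = 1, note_length_tokens = c(80, 160),
    signature_injection_rate = 1))
  sp <- notemia:::split_corpus(corp)
  m <- train_classifier(sp$train, sp$val, u, classifier_config(
    epochs = 15, max_note_tokens = 128, patience = 0, seed = 2))
  pr <- predict_probabilities(m, sp$test)
  y <- notemia:::label_matrix(sp$test, u$code)
  rep_ <- micro_macro_report(y, pr, quiet = TRUE)
  expect_gte(rep_$micro[["f1"]], 0.80)
})

test_that("a no-signal corpus scores near chance per label", {
  # with zero injection the text carries no label information; the
  # prevalence-blind macro AUC must sit near 0.5 (the pooled micro AUC
  # legitimately exceeds 0.5 because skewed prevalence is itself an
  # informative prior across labels)
  u <- build_code_universe(n_codes = 10, seed = 5)
  corp <- generate_corpus(u, corpus_config(
    n_notes = 200, seed = 5, note_length_tokens = c(40, 80),
    signature_injection_rate = 0))
  sp <- notemia:::split_corpus(corp)
  m <- train_classifier(sp$train, sp$val, u, classifier_config(
    epochs = 5, max_note_tokens = 64, patience = 0, seed = 6))
  pr <- predict_probabilities(m, sp$test)
  y <- notemia:::label_matrix(sp$test, u$code)
  rep_ <- micro_macro_report(y, pr, quiet = TRUE)
  expect_lt(abs(rep_$macro[["auc"]] - 0.5), 0.1)
})

test_that("shrinking the token cap does not improve mean utility", {
  # signatures are spread across the note, so truncation loses signal:
  # mean micro-F1 over seeds should be non-increasing in expectation as
  # the cap shrinks 64 -> 32 -> 16
  u <- build_code_universe(n_codes = 10, seed = 3)
  caps <- c(64, 32, 16)
  f1 <- matrix(0, 5, length(caps))
  for (s in 1:5) {
    corp <- generate_corpus(u, corpus_config(
      n_notes = 150, seed = 300 + s, note_length_tokens = c(50, 70)))
    sp <- notemia:::split_corpus(corp)
    y <- notemia:::label_matrix(sp$test, u$code)
    for (ci in seq_along(caps)) {
      m <- train_classifier(sp$train, sp$val, u, classifier_config(
        epochs = 8, max_note_tokens = caps[ci], patience = 0, seed = s))
      pr <- predict_probabilities(m, sp$test)
      f1[s, ci] <- micro_macro_report(y, pr, quiet = TRUE)$micro[["f1"]]
    }
  }
  means <- colMeans(f1)
  expect_true(all(diff(means) <= 0.02),
              label = paste("mean micro-F1 by cap:",
                            paste(round(means, 3), collapse = " ")))
})
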