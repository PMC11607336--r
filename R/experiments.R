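# Experiment orchestration: the real-trained-victim audit, the
# synthetic-trained-victim audit, and the privacy-utility trade-off
# sweeps over training-set size, note length and key-phrase count.

split_corpus <- function(corpus) {
  list(train = corpus[corpus$split == "train", , drop = FALSE],
       val = corpus[corpus$split == "val", , drop = FALSE],
       test = corpus[corpus$split == "test", , drop = FALSE])
}

# ks restricted to the label count, so small desk universes still work.
.usable_ks <- function(L, ks = c(1, 5, 8, 10, 15)) ks[ks <= L]

#' Audit a victim trained on real notes
#'
#' Trains the victim classifier on the corpus's train split (early
#' stopping on the validation split), evaluates utility on the test
#' split, builds the membership dataset from the victim's prediction
#' vectors for the train (member) and test (non-member) notes, and runs
#' the attack suite.
#'
#' @param corpus a `note_corpus` with train/val/test splits.
#' @param universe the `code_universe`.
#' @param classifier_cfg a `classifier_config`.
#' @param attack_cfg an `attack_config`.
#' @param ks precision-at-k values (those exceeding the label count are
#'   dropped).
#' @param out_dir optional directory; when given, prediction matrices
#'   and a JSON report are persisted there.
#' @return a list of class `experiment_result`: `utility`
#'   (a `utility_report`), `attack` (an `attack_report`), `model`,
#'   `member_preds`, `nonmember_preds`.
#' @export
run_real_experiment <- function(corpus, universe,
                                classifier_cfg = classifier_config(),
                                attack_cfg = attack_config(),
                                ks = c(1, 5, 8, 10, 15),
                                out_dir = NULL) {
  sp <- split_corpus(corpus)
  model <- train_classifier(sp$train, sp$val, universe, classifier_cfg)
  test_prob <- predict_probabilities(model, sp$test)
  y_test <- label_matrix(sp$test, universe$code)
  utility <- utility_report(y_test, test_prob,
                            threshold = classifier_cfg$decision_threshold,
                            ks = .usable_ks(nrow(universe), ks),
                            quiet = TRUE)
  member_preds <- predict_probabilities(model, sp$train)
  ds <- membership_dataset(member_preds, test_prob,
                           multilabel = attack_cfg$multilabel)
  attack <- run_attack_suite(ds, attack_cfg)
  res <- structure(list(utility = utility, attack = attack, model = model,
                        member_preds = member_preds,
                        nonmember_preds = test_prob),
                   class = "experiment_result")
  if (!is.null(out_dir)) persist_experiment(res, out_dir)
  res
}

#' Audit a victim trained on synthetic notes
#'
#' The synthetic-data audit: key phrases are extracted from the real
#' train and validation notes and synthetic replacements generated
#' through the backend (ids, labels and splits preserved).  The victim
#' trains on the synthetic train/val notes and never sees real training
#' text.  Utility is evaluated on the REAL test notes, and the
#' membership dataset pairs the victim's prediction vectors for the REAL
#' train notes (members) against the REAL test notes (non-members).
#'
#' @inheritParams run_real_experiment
#' @param extractor_cfg an `extractor_config` for phrase extraction.
#' @param backend a `generation_backend` (default the stub).
#' @param variant prompt variant.
#' @param top_n phrases per prompt.
#' @param gen_seed seed for the generation stage.
#' @return an `experiment_result` with an extra `synthetic` element
#'   holding the synthetic corpus.
#' @export
run_synthetic_experiment <- function(corpus, universe,
                                     extractor_cfg = extractor_config(),
                                     backend = stub_backend(),
                                     classifier_cfg = classifier_config(),
                                     attack_cfg = attack_config(),
                                     variant = "v0613",
                                     top_n = extractor_cfg$top_n,
                                     gen_seed = 1,
                                     ks = c(1, 5, 8, 10, 15),
                                     out_dir = NULL) {
  sp <- split_corpus(corpus)
  real_trainval <- rbind(sp$train, sp$val)
  synth <- synthesize_corpus(real_trainval, extractor_cfg,
                             backend = backend, variant = variant,
                             top_n = top_n, seed = gen_seed)
  ssp <- split_corpus(synth)
  model <- train_classifier(ssp$train, ssp$val, universe, classifier_cfg)

  test_prob <- predict_probabilities(model, sp$test)
  y_test <- label_matrix(sp$test, universe$code)
  utility <- utility_report(y_test, test_prob,
                            threshold = classifier_cfg$decision_threshold,
                            ks = .usable_ks(nrow(universe), ks),
                            quiet = TRUE)
  member_preds <- predict_probabilities(model, sp$train)
  ds <- membership_dataset(member_preds, test_prob,
                           multilabel = attack_cfg$multilabel)
  attack <- run_attack_suite(ds, attack_cfg)
  res <- structure(list(utility = utility, attack = attack, model = model,
                        member_preds = member_preds,
                        nonmember_preds = test_prob, synthetic = synth),
                   class = "experiment_result")
  if (!is.null(out_dir)) persist_experiment(res, out_dir)
  res
}

persist_experiment <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_prediction_matrix(rownames(res$member_preds), res$member_preds,
                          file.path(out_dir, "member_preds.tsv"))
  write_prediction_matrix(rownames(res$nonmember_preds),
                          res$nonmember_preds,
                          file.path(out_dir, "nonmember_preds.tsv"))
  report <- list(
    utility = list(micro = as.list(res$utility$micro),
                   macro = as.list(res$utility$macro),
                   p_at_k = as.list(res$utility$p_at_k)),
    attack = lapply(res$attack$models, function(m) {
      list(advantage = m$metrics$advantage, auc = m$metrics$auc)
    }),
    best_attack = res$attack$best
  )
  writeLines(jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA),
             file.path(out_dir, "report.json"))
  invisible(out_dir)
}

#' @export
print.experiment_result <- function(x, ...) {
  print(x$utility)
  print(x$attack)
  invisible(x)
}

# One result row for the sweep table.
sweep_row <- function(size, max_tokens, top_n, seed, res) {
  u <- res$utility
  row <- data.frame(
    size = size, max_tokens = max_tokens, top_n = top_n, seed = seed,
    micro_auc = u$micro[["auc"]], micro_precision = u$micro[["precision"]],
    micro_recall = u$micro[["recall"]], micro_f1 = u$micro[["f1"]],
    macro_auc = u$macro[["auc"]], macro_precision = u$macro[["precision"]],
    macro_recall = u$macro[["recall"]], macro_f1 = u$macro[["f1"]],
    advantage = res$attack$best_advantage,
    attack_auc = res$attack$best_auc,
    stringsAsFactors = FALSE
  )
  for (nm in names(u$p_at_k)) row[[nm]] <- u$p_at_k[[nm]]
  row
}

#' Privacy-utility trade-off sweep
#'
#' Repeats the real-victim audit (`kind = "real"`) over every
#' combination of training-set size and note-length cap, or the
#' synthetic-victim audit (`kind = "synthetic"`) over every combination
#' of training-set size and key-phrase count, each with
#' `n_seed_replicates` seed replicates.  Emits one detail row per
#' (configuration, seed) plus mean/sd summary rows per configuration,
#' sorted by size then length (or phrase count) descending.
#'
#' @param corpus a `note_corpus`.
#' @param universe the `code_universe`.
#' @param sweep list with `training_set_sizes`, `max_note_tokens`,
#'   `key_phrase_counts`, `n_seed_replicates` (see [default_config()]).
#' @param kind `"real"` or `"synthetic"`.
#' @param classifier_cfg base `classifier_config` (size/length/seed are
#'   overridden per row).
#' @param attack_cfg base `attack_config`.
#' @param extractor_cfg `extractor_config` for `kind = "synthetic"`.
#' @param backend generation backend for `kind = "synthetic"`.
#' @param seed master seed; per-row seeds derive from it.
#' @return a data.frame of detail and summary rows (`stat` column:
#'   `"seed"`, `"mean"` or `"sd"`).
#' @export
run_tradeoff_sweep <- function(corpus, universe, sweep,
                               kind = c("real", "synthetic"),
                               classifier_cfg = classifier_config(),
                               attack_cfg = attack_config(),
                               extractor_cfg = extractor_config(),
                               backend = stub_backend(), seed = 1) {
  kind <- match.arg(kind)
  sp <- split_corpus(corpus)
  if (any(sweep$training_set_sizes > nrow(sp$train))) {
    stop("a requested training size exceeds the available training notes")
  }
  second_axis <- if (kind == "real") sweep$max_note_tokens else
    sweep$key_phrase_counts
  rows <- list()
  for (size in sort(sweep$training_set_sizes, decreasing = TRUE)) {
    for (ax in sort(second_axis, decreasing = TRUE)) {
      detail <- list()
      for (r in seq_len(sweep$n_seed_replicates)) {
        tag <- sprintf("sweep/%s/%d/%d/%d", kind, size, ax, r)
        rs <- child_seed(seed, tag)
        sub <- corpus
        keep <- with_seed(child_seed(seed, paste0(tag, "/subsample")), {
          sample(which(corpus$split == "train"), size)
        })
        sub <- corpus[sort(c(keep, which(corpus$split != "train"))), ,
                      drop = FALSE]
        ccfg <- classifier_cfg
        ccfg$seed <- rs
        acfg <- attack_cfg
        acfg$seed <- child_seed(rs, "attack")
        res <- if (kind == "real") {
          ccfg$max_note_tokens <- as.integer(ax)
          run_real_experiment(sub, universe, ccfg, acfg)
        } else {
          run_synthetic_experiment(sub, universe, extractor_cfg,
                                   backend = backend,
                                   classifier_cfg = ccfg,
                                   attack_cfg = acfg, top_n = ax,
                                   gen_seed = rs)
        }
        row <- sweep_row(size,
                         if (kind == "real") ax else
                           classifier_cfg$max_note_tokens,
                         if (kind == "real") NA_integer_ else ax,
                         rs, res)
        detail[[r]] <- row
      }
      detail <- do.call(rbind, detail)
      detail$stat <- "seed"
      num_cols <- setdiff(names(detail),
                          c("size", "max_tokens", "top_n", "seed", "stat"))
      summ <- detail[1:2, , drop = FALSE]
      summ$seed <- NA_integer_
      summ$stat <- c("mean", "sd")
      for (cn in num_cols) {
        summ[[cn]] <- c(mean(detail[[cn]]), stats::sd(detail[[cn]]))
      }
      rows[[length(rows) + 1L]] <- rbind(detail, summ)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
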