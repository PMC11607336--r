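# Membership-inference attack framework: attack-data balancing, the
# stratified two-fold score-assignment protocol with leftover handling,
# five attack models, and reporting.
#
# Convention throughout: membership scores are oriented so that larger
# means more member-like; trained attackers output the member-class
# probability.

.attack_model_order <- c("threshold", "logistic", "knn", "random_forest",
                         "mlp")

#' Attack configuration
#'
#' @param attack_models subset of `"threshold"`, `"logistic"`, `"knn"`,
#'   `"random_forest"`, `"mlp"` (default: all five).
#' @param balance balance member/non-member counts before attacker
#'   training (default `TRUE`).
#' @param n_folds stratified folds for score assignment (default 2).
#' @param multilabel treat prediction vectors as multilabel output
#'   (identity features); otherwise features are the descending-sorted
#'   probabilities (default `TRUE`).
#' @param seed integer seed.
#' @return a list of class `attack_config`.
#' @export
attack_config <- function(attack_models = .attack_model_order,
                          balance = TRUE, n_folds = 2, multilabel = TRUE,
                          seed = 1) {
  attack_models <- match.arg(attack_models, .attack_model_order,
                             several.ok = TRUE)
  if (length(attack_models) < 1) stop("need at least one attack model")
  if (n_folds < 2) stop("`n_folds` must be >= 2")
  structure(list(attack_models = attack_models, balance = balance,
                 n_folds = as.integer(n_folds), multilabel = multilabel,
                 seed = as.integer(seed)),
            class = "attack_config")
}

#' Assemble a membership dataset
#'
#' Victim prediction vectors partitioned into members (the victim's
#' training notes) and non-members (held-out notes).
#'
#' @param member_vectors numeric matrix `m x L` of probabilities.
#' @param nonmember_vectors numeric matrix `k x L`.
#' @param multilabel flag recorded with the data (default `TRUE`).
#' @return a list of class `membership_dataset`.
#' @export
membership_dataset <- function(member_vectors, nonmember_vectors,
                               multilabel = TRUE) {
  member_vectors <- as.matrix(member_vectors)
  nonmember_vectors <- as.matrix(nonmember_vectors)
  if (ncol(member_vectors) != ncol(nonmember_vectors)) {
    stop("member and non-member vectors must share the label dimension")
  }
  if (nrow(member_vectors) < 1 || nrow(nonmember_vectors) < 1) {
    stop("both groups must be non-empty")
  }
  rng <- range(member_vectors, nonmember_vectors)
  if (rng[1] < 0 || rng[2] > 1) stop("prediction values must be in [0, 1]")
  structure(list(member = member_vectors, nonmember = nonmember_vectors,
                 multilabel = multilabel),
            class = "membership_dataset")
}

#' Balance the attacker's training data
#'
#' Keeps `min(m, k)` samples per class; the larger class is subsampled
#' by uniform random sampling without replacement and its unused rows
#' are recorded as leftovers.
#'
#' @param dataset a `membership_dataset`.
#' @param seed optional integer seed; `NULL` uses the current RNG
#'   stream.
#' @return a list of class `balanced_attack_data`: `member_idx`,
#'   `nonmember_idx` (each of length `min(m, k)`, ascending),
#'   `leftover_group` and `leftover_idx`.
#' @export
#' @examples
#' d <- membership_dataset(matrix(runif(10), 5), matrix(runif(6), 3))
#' balance_attack_data(d, seed = 1)
balance_attack_data <- function(dataset, seed = NULL) {
  m <- nrow(dataset$member)
  k <- nrow(dataset$nonmember)
  n <- min(m, k)
  draw <- function() {
    mi <- if (m > n) sort(sample.int(m, n)) else seq_len(m)
    ki <- if (k > n) sort(sample.int(k, n)) else seq_len(k)
    list(mi = mi, ki = ki)
  }
  sel <- if (is.null(seed)) draw() else with_seed(seed, draw())
  leftover_group <- if (m > k) "member" else if (k > m) "nonmember" else
    "none"
  leftover_idx <- switch(leftover_group,
    member = setdiff(seq_len(m), sel$mi),
    nonmember = setdiff(seq_len(k), sel$ki),
    none = integer(0))
  structure(list(member_idx = sel$mi, nonmember_idx = sel$ki,
                 leftover_group = leftover_group,
                 leftover_idx = leftover_idx),
            class = "balanced_attack_data")
}

#' Attack feature mapping
#'
#' With `multilabel = TRUE` the full probability vector is used as-is;
#' otherwise each row is sorted into descending order (the attacker then
#' sees confidence shape, not label identity).
#'
#' @param vectors numeric matrix (rows = samples) or a single vector.
#' @param multilabel flag.
#' @return the feature matrix.
#' @export
attack_features <- function(vectors, multilabel = TRUE) {
  v <- if (is.null(dim(vectors))) matrix(vectors, nrow = 1) else
    as.matrix(vectors)
  if (multilabel) return(v)
  t(apply(v, 1, sort, decreasing = TRUE))
}

#' Threshold (model-free) membership score
#'
#' Scores every sample by its mean per-label confidence margin
#' `mean(|p - 0.5|)`: a victim is typically more confident — probabilities
#' nearer 0 or 1 — on notes it was trained on.  No model is fitted.
#'
#' @param dataset a `membership_dataset`.
#' @return a data.frame with `group`, `index`, `score`, one row per
#'   sample (`m + k` rows).
#' @export
threshold_attack <- function(dataset) {
  margin <- function(x) rowMeans(abs(x - 0.5))
  data.frame(
    group = c(rep("member", nrow(dataset$member)),
              rep("nonmember", nrow(dataset$nonmember))),
    index = c(seq_len(nrow(dataset$member)),
              seq_len(nrow(dataset$nonmember))),
    score = c(margin(dataset$member), margin(dataset$nonmember)),
    stringsAsFactors = FALSE
  )
}

# Fit one attack model; returns a scoring closure newx -> P(member).
fit_attack_model <- function(x, y, model_type, seed) {
  switch(model_type,
    logistic = {
      df <- as.data.frame(x)
      names(df) <- paste0("f", seq_len(ncol(x)))
      df$.y <- y
      fit <- suppressWarnings(glm(.y ~ ., data = df, family = binomial()))
      function(newx) {
        nd <- as.data.frame(newx)
        names(nd) <- paste0("f", seq_len(ncol(newx)))
        suppressWarnings(unname(predict(fit, nd, type = "response")))
      }
    },
    knn = {
      function(newx) {
        with_seed(seed, {
          pr <- class::knn(x, newx, factor(y, levels = c(0, 1)), k = 5,
                           prob = TRUE)
          p <- attr(pr, "prob")
          ifelse(pr == "1", p, 1 - p)
        })
      }
    },
    random_forest = {
      fit <- with_seed(seed, randomForest::randomForest(
        x = x, y = factor(y, levels = c(0, 1)), ntree = 100))
      function(newx) unname(predict(fit, newx, type = "prob")[, "1"])
    },
    mlp = {
      fit <- with_seed(seed, nnet::nnet(
        x = x, y = y, size = 8, decay = 1e-3, maxit = 200,
        entropy = TRUE, trace = FALSE))
      function(newx) as.vector(predict(fit, newx))
    },
    stop(sprintf("unknown attack model '%s'", model_type))
  )
}

# Contiguous stratified fold assignment by position in original order
# (the "unshuffled" convention: fold f holds the f-th positional block
# of each class).
stratified_folds <- function(n, n_folds) {
  sizes <- rep(n %/% n_folds, n_folds)
  extra <- n %% n_folds
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  rep(seq_len(n_folds), sizes)
}

#' Run one trained attack with fold-based score assignment
#'
#' Balanced samples are split into `n_folds` stratified, unshuffled
#' folds (assignment by position within each class in original input
#' order).  For each fold, an attacker of `model_type` is trained on the
#' remaining folds and scores the held-out fold.  Leftover samples from
#' the larger class are scored by the attacker of the final fold.  Every
#' sample receives exactly one score.
#'
#' @param dataset a `membership_dataset`.
#' @param model_type one of `"logistic"`, `"knn"`, `"random_forest"`,
#'   `"mlp"` (use [threshold_attack()] for the model-free attack).
#' @param config an `attack_config`.
#' @return a data.frame with `group`, `index`, `score` covering all
#'   `m + k` samples.
#' @export
run_trained_attack <- function(dataset, model_type,
                               config = attack_config()) {
  bal <- balance_attack_data(dataset,
                             seed = child_seed(config$seed, "balance"))
  n <- length(bal$member_idx)
  if (n < config$n_folds) {
    stop("too few balanced samples for the requested fold count")
  }
  feats_m <- attack_features(dataset$member, config$multilabel)
  feats_k <- attack_features(dataset$nonmember, config$multilabel)

  fold <- stratified_folds(n, config$n_folds)  # same blocks per class
  scores <- data.frame(group = character(0), index = integer(0),
                       score = numeric(0), stringsAsFactors = FALSE)
  last_model <- NULL
  for (f in seq_len(config$n_folds)) {
    tr_m <- bal$member_idx[fold != f]
    tr_k <- bal$nonmember_idx[fold != f]
    te_m <- bal$member_idx[fold == f]
    te_k <- bal$nonmember_idx[fold == f]
    if (length(tr_m) == 0 || length(tr_k) == 0) {
      stop("a training fold lost one class; reduce `n_folds`")
    }
    x <- rbind(feats_m[tr_m, , drop = FALSE],
               feats_k[tr_k, , drop = FALSE])
    y <- c(rep(1, length(tr_m)), rep(0, length(tr_k)))
    model <- fit_attack_model(
      x, y, model_type,
      child_seed(config$seed, paste0("fit/", model_type, "/", f)))
    newx <- rbind(feats_m[te_m, , drop = FALSE],
                  feats_k[te_k, , drop = FALSE])
    s <- model(newx)
    scores <- rbind(scores, data.frame(
      group = c(rep("member", length(te_m)),
                rep("nonmember", length(te_k))),
      index = c(te_m, te_k), score = s, stringsAsFactors = FALSE))
    last_model <- model
  }
  if (length(bal$leftover_idx) > 0) {
    lx <- if (bal$leftover_group == "member") {
      feats_m[bal$leftover_idx, , drop = FALSE]
    } else {
      feats_k[bal$leftover_idx, , drop = FALSE]
    }
    scores <- rbind(scores, data.frame(
      group = bal$leftover_group, index = bal$leftover_idx,
      score = last_model(lx), stringsAsFactors = FALSE))
  }
  rownames(scores) <- NULL
  scores
}

#' Run the configured attack suite
#'
#' Runs every configured attack model, computes [attack_metrics()] per
#' model over all `m + k` membership scores, and selects the best model
#' by attacker advantage (ties broken by the canonical model order).
#'
#' @param dataset a `membership_dataset`.
#' @param config an `attack_config`.
#' @return a list of class `attack_report`: `models` (per model:
#'   `metrics` and the per-sample `scores` data.frame), `best` (model
#'   name), `best_advantage`, `best_auc`.
#' @export
run_attack_suite <- function(dataset, config = attack_config()) {
  results <- list()
  for (mt in config$attack_models) {
    scores <- if (mt == "threshold") {
      threshold_attack(dataset)
    } else {
      run_trained_attack(dataset, mt, config)
    }
    metrics <- attack_metrics(scores$score,
                              as.integer(scores$group == "member"))
    results[[mt]] <- list(metrics = metrics, scores = scores)
  }
  adv <- vapply(results, function(r) r$metrics$advantage, numeric(1))
  ordered <- intersect(.attack_model_order, names(results))
  best <- ordered[which.max(adv[ordered])]
  structure(list(models = results, best = best,
                 best_advantage = results[[best]]$metrics$advantage,
                 best_auc = results[[best]]$metrics$auc),
            class = "attack_report")
}

#' @export
print.attack_report <- function(x, ...) {
  cat("membership-inference attack report\n")
  for (mt in names(x$models)) {
    m <- x$models[[mt]]$metrics
    cat(sprintf("  %-13s advantage %.4f  AUC %.4f%s\n", mt, m$advantage,
                m$auc, if (mt == x$best) "  <- best" else ""))
  }
  invisible(x)
}
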