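# Utility and attack metrics: micro/macro-averaged AUC, precision,
# recall and F1 over (note, code) pairs, precision-at-k, and the
# ROC-derived attack metrics (attacker advantage = max TPR - FPR, AUC).

# ROC curve over all score thresholds with tied scores grouped.
# Returns points ordered from (0,0) to (1,1).
roc_points <- function(scores, labels) {
  if (length(unique(labels)) < 2) {
    stop("both classes must be present to compute ROC metrics")
  }
  pos <- sum(labels == 1)
  neg <- sum(labels == 0)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  # group tied scores: cumulative counts at each distinct threshold
  grp <- cumsum(!duplicated(s))
  tp <- tapply(y == 1, grp, sum)
  fp <- tapply(y == 0, grp, sum)
  data.frame(
    tpr = c(0, cumsum(tp) / pos),
    fpr = c(0, cumsum(fp) / neg)
  )
}

# 0/0 -> 0 convention for degenerate denominators.
.safe_div <- function(num, den) if (den == 0) 0 else num / den

# Binary precision/recall/F1 at a threshold, pooled over a vector.
binary_prf <- function(truth, prob, threshold) {
  pred <- prob >= threshold
  tp <- sum(pred & truth == 1)
  p <- .safe_div(tp, sum(pred))
  r <- .safe_div(tp, sum(truth == 1))
  f <- .safe_div(2 * p * r, p + r)
  c(precision = p, recall = r, f1 = f)
}

# Threshold-free AUC with mid-rank tie handling (trapezoid over the
# grouped ROC; equals the Mann-Whitney statistic).
binary_auc <- function(truth, prob) {
  rp <- roc_points(prob, truth)
  sum(diff(rp$fpr) * (utils::head(rp$tpr, -1) + rp$tpr[-1]) / 2)
}

#' Micro- and macro-averaged utility report
#'
#' Micro values treat every (note, code) pair as one prediction and pool
#' all `n * L` pairs; macro values compute each metric per label and take
#' the unweighted mean.  Precision, recall and F1 binarize at
#' `threshold`; AUC is threshold-free with mid-rank tie handling (a
#' constant score column gives AUC 0.5).  Labels with a single class in
#' `y_true` have no defined AUC and are excluded from the macro AUC mean;
#' the count of exclusions is reported and messaged.
#'
#' @param y_true binary matrix (`n x L`).
#' @param y_prob probability matrix (`n x L`) in `[0, 1]`.
#' @param threshold decision threshold for P/R/F1 (default 0.5).
#' @param quiet suppress the excluded-label message.
#' @return a list of class `utility_report` with elements `micro`,
#'   `macro` (named vectors: auc, precision, recall, f1),
#'   `n_excluded_auc_labels`, `n_notes`, `n_labels`,
#'   `decision_threshold`.
#' @export
micro_macro_report <- function(y_true, y_prob, threshold = 0.5,
                               quiet = FALSE) {
  y_true <- as.matrix(y_true)
  y_prob <- as.matrix(y_prob)
  if (!all(dim(y_true) == dim(y_prob))) {
    stop("`y_true` and `y_prob` must have identical dimensions")
  }
  if (threshold <= 0 || threshold >= 1) stop("`threshold` must be in (0,1)")
  L <- ncol(y_true)

  micro <- c(auc = binary_auc(as.vector(y_true), as.vector(y_prob)),
             binary_prf(as.vector(y_true), as.vector(y_prob), threshold))

  per_label <- vapply(seq_len(L), function(j) {
    prf <- binary_prf(y_true[, j], y_prob[, j], threshold)
    auc <- if (length(unique(y_true[, j])) < 2) NA_real_ else {
      binary_auc(y_true[, j], y_prob[, j])
    }
    c(auc = auc, prf)
  }, numeric(4))
  n_excl <- sum(is.na(per_label["auc", ]))
  if (n_excl > 0 && !quiet) {
    message(sprintf(
      "%d label(s) without both classes excluded from macro AUC", n_excl))
  }
  macro <- c(auc = mean(per_label["auc", ], na.rm = TRUE),
             precision = mean(per_label["precision", ]),
             recall = mean(per_label["recall", ]),
             f1 = mean(per_label["f1", ]))

  structure(list(micro = micro, macro = macro,
                 n_excluded_auc_labels = n_excl,
                 n_notes = nrow(y_true), n_labels = L,
                 decision_threshold = threshold),
            class = "utility_report")
}

#' @export
print.utility_report <- function(x, ...) {
  cat(sprintf("utility report: %d notes x %d labels (threshold %.2f)\n",
              x$n_notes, x$n_labels, x$decision_threshold))
  tab <- rbind(micro = x$micro, macro = x$macro)
  print(round(tab, 4))
  if (!is.null(x$p_at_k)) {
    cat("precision at k:\n")
    print(round(x$p_at_k, 4))
  }
  invisible(x)
}

#' Precision at k
#'
#' For each note, the fraction of its `k` highest-probability labels
#' that are true, averaged over notes.  Ties in probability are broken
#' by label index.
#'
#' @param y_true binary matrix (`n x L`).
#' @param y_prob probability matrix (`n x L`).
#' @param ks the k values (default `c(1, 5, 8, 10, 15)`); every k must
#'   be `<= L`.
#' @return named numeric vector, one value per k.
#' @export
precision_at_k <- function(y_true, y_prob, ks = c(1, 5, 8, 10, 15)) {
  y_true <- as.matrix(y_true)
  y_prob <- as.matrix(y_prob)
  L <- ncol(y_true)
  if (any(ks > L)) stop("every k must be <= the number of labels")
  if (any(ks < 1)) stop("k must be >= 1")
  out <- vapply(ks, function(k) {
    hits <- vapply(seq_len(nrow(y_prob)), function(i) {
      top <- order(-y_prob[i, ], seq_len(L))[seq_len(k)]
      sum(y_true[i, top]) / k
    }, numeric(1))
    mean(hits)
  }, numeric(1))
  names(out) <- paste0("p_at_", ks)
  out
}

#' Full utility report including precision at k
#'
#' Convenience wrapper combining [micro_macro_report()] and
#' [precision_at_k()] into one report object.
#'
#' @inheritParams micro_macro_report
#' @param ks k values for precision-at-k; values exceeding the label
#'   count are dropped with a message.
#' @return a `utility_report` with an additional `p_at_k` element.
#' @export
utility_report <- function(y_true, y_prob, threshold = 0.5,
                           ks = c(1, 5, 8, 10, 15), quiet = FALSE) {
  rep_ <- micro_macro_report(y_true, y_prob, threshold, quiet = quiet)
  ks_ok <- ks[ks <= ncol(as.matrix(y_true))]
  if (length(ks_ok) < length(ks) && !quiet) {
    message("dropping k values exceeding the label count")
  }
  rep_$p_at_k <- precision_at_k(y_true, y_prob, ks_ok)
  rep_
}

#' Membership-attack metrics
#'
#' ROC over all score thresholds (tied scores grouped), attacker
#' advantage `max(TPR - FPR)` over the curve, and trapezoid AUC.  The
#' advantage is never negative: the degenerate all-or-nothing threshold
#' achieves 0.
#'
#' @param scores real-valued membership scores (larger = more
#'   member-like).
#' @param membership_labels binary labels, member = 1.
#' @return a list of class `attack_metrics` with `advantage`, `auc` and
#'   the `roc` points data.frame.
#' @export
#' @examples
#' attack_metrics(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
attack_metrics <- function(scores, membership_labels) {
  rp <- roc_points(scores, membership_labels)
  structure(list(
    advantage = max(rp$tpr - rp$fpr),
    auc = sum(diff(rp$fpr) * (utils::head(rp$tpr, -1) + rp$tpr[-1]) / 2),
    roc = rp
  ), class = "attack_metrics")
}

#' @export
print.attack_metrics <- function(x, ...) {
  cat(sprintf("attack metrics: advantage %.4f, AUC %.4f (%d ROC points)\n",
              x$advantage, x$auc, nrow(x$roc)))
  invisible(x)
}
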