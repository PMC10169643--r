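#' Classification metrics for association prediction
#'
#' Computes the four standard metrics of this task and their mean:
#' \itemize{
#'   \item AUC by the rank statistic (Mann-Whitney), ties counted 0.5;
#'   \item AUPR by the average-precision convention, i.e. the area under the
#'     precision-recall step curve with no interpolation;
#'   \item F1 and MCC from the confusion matrix at `threshold` (predict
#'     positive when `score >= threshold`); MCC is defined as 0 when its
#'     denominator vanishes, F1 as 0 when no true or predicted positives
#'     exist.
#' }
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (0/1), same length.
#' @param threshold Classification cut-off for F1/MCC.
#' @return A list of class `"ldra_metrics"`: `auc`, `aupr`, `f1`, `mcc`,
#'   `average_metric` (mean of the four), `n_pos`, `n_neg`, `threshold`.
#' @export
#' @examples
#' compute_metrics(c(0.9, 0.8, 0.7, 0.1), c(1, 0, 1, 0))
compute_metrics <- function(scores, labels, threshold = 0.5) {
  if (length(scores) != length(labels)) {
    ldra_error("ldra_contract_error", "scores and labels differ in length")
  }
  if (!all(labels %in% c(0, 1))) {
    ldra_error("ldra_contract_error", "labels must be 0 or 1")
  }
  labels <- as.integer(labels)
  np <- sum(labels == 1L)
  nn <- sum(labels == 0L)
  if (np == 0L || nn == 0L) {
    ldra_error("ldra_metric_error", "need both classes to compute metrics")
  }

  r <- rank(scores)  # average ranks => ties count 0.5 in the AUC
  auc <- (sum(r[labels == 1L]) - np * (np + 1) / 2) / (np * nn)

  ord <- order(-scores)
  y <- labels[ord]
  s <- scores[ord]
  tp <- cumsum(y)
  fp <- cumsum(1L - y)
  # collapse tied scores: evaluate at the last position of each tie group
  last <- c(s[-1] != s[-length(s)], TRUE)
  prec <- tp[last] / (tp[last] + fp[last])
  rec <- tp[last] / np
  aupr <- sum(diff(c(0, rec)) * prec)

  pred <- as.integer(scores >= threshold)
  TP <- sum(pred == 1L & labels == 1L)
  FP <- sum(pred == 1L & labels == 0L)
  FN <- sum(pred == 0L & labels == 1L)
  TN <- sum(pred == 0L & labels == 0L)
  f1 <- if (2 * TP + FP + FN == 0) 0 else 2 * TP / (2 * TP + FP + FN)
  den <- sqrt(as.numeric(TP + FP)) * sqrt(as.numeric(TP + FN)) *
    sqrt(as.numeric(TN + FP)) * sqrt(as.numeric(TN + FN))
  mcc <- if (den == 0) 0 else (as.numeric(TP) * TN - as.numeric(FP) * FN) / den

  out <- list(auc = auc, aupr = aupr, f1 = f1, mcc = mcc,
              average_metric = (auc + aupr + f1 + mcc) / 4,
              n_pos = np, n_neg = nn, threshold = threshold)
  class(out) <- "ldra_metrics"
  out
}

#' @export
print.ldra_metrics <- function(x, ...) {
  cat(sprintf("AUC %.4f | AUPR %.4f | F1 %.4f | MCC %.4f | average %.4f  (%d pos / %d neg, threshold %.2f)\n",
              x$auc, x$aupr, x$f1, x$mcc, x$average_metric,
              x$n_pos, x$n_neg, x$threshold))
  invisible(x)
}

#' Build cross-validation folds over association-matrix entries
#'
#' Positives are shuffled by `seed` and dealt round-robin into `k` test sets
#' (sizes differ by at most 1), so the test positives partition all
#' positives. Negative assignment depends on `mode`:
#' \describe{
#'   \item{`unbalanced`}{every non-positive pair is used — shuffled and dealt
#'     round-robin into the folds' test sets, with the remainder of each fold
#'     forming its training negatives;}
#'   \item{`balanced`}{per fold, as many negatives as positives are sampled
#'     uniformly without replacement (test and training sets disjoint), with
#'     explicitly 0-labelled known negatives preferred over merely unobserved
#'     pairs.}
#' }
#'
#' @param matrix An `"assoc_matrix"`.
#' @param k Number of folds (default 10).
#' @param mode `"balanced"` or `"unbalanced"`.
#' @param seed Seed for shuffling and sampling.
#' @return A list of class `"ldra_folds"`; each fold is a list with
#'   `fold_id`, `train_pos`, `test_pos`, `train_neg`, `test_neg` (two-column
#'   index matrices) and `mode`.
#' @export
make_folds <- function(matrix, k = 10L, mode = c("balanced", "unbalanced"),
                       seed = 1L) {
  mode <- match.arg(mode)
  am <- as_association_matrix(matrix)
  A <- am$A
  m <- nrow(A)
  pos_lin <- which(as.vector(A) == 1)
  npos <- length(pos_lin)
  k <- as.integer(k)
  if (k < 2L || k > npos) {
    ldra_error("ldra_fold_error", "k must satisfy 2 <= k <= number of positives (%d)", npos)
  }
  neg_lin <- which(as.vector(A) == 0)
  known_neg_lin <- if (nrow(am$known_neg)) pairs_to_linear(am$known_neg, m) else integer(0)
  known_neg_lin <- intersect(known_neg_lin, neg_lin)
  unknown_neg_lin <- setdiff(neg_lin, known_neg_lin)

  with_seed(seed, {
    pos_sh <- sample(pos_lin)
    fold_of_pos <- (seq_len(npos) - 1L) %% k
    folds <- vector("list", k)
    if (mode == "unbalanced") {
      neg_sh <- sample(neg_lin)
      fold_of_neg <- (seq_along(neg_sh) - 1L) %% k
    }
    for (f in seq_len(k) - 1L) {
      test_pos <- pos_sh[fold_of_pos == f]
      train_pos <- pos_sh[fold_of_pos != f]
      if (mode == "unbalanced") {
        test_neg <- neg_sh[fold_of_neg == f]
        train_neg <- neg_sh[fold_of_neg != f]
      } else {
        need <- length(test_pos) + length(train_pos)
        if (need > length(neg_lin)) {
          ldra_error("ldra_fold_error",
                     "not enough negative pairs (%d) for balanced folds (%d needed)",
                     length(neg_lin), need)
        }
        pool <- c(sample(known_neg_lin), sample(unknown_neg_lin))
        test_neg <- pool[seq_len(length(test_pos))]
        train_neg <- pool[length(test_pos) + seq_len(length(train_pos))]
      }
      folds[[f + 1L]] <- list(
        fold_id = f,
        train_pos = linear_to_pairs(train_pos, m),
        test_pos = linear_to_pairs(test_pos, m),
        train_neg = linear_to_pairs(train_neg, m),
        test_neg = linear_to_pairs(test_neg, m),
        mode = mode
      )
    }
    structure(folds, class = "ldra_folds", m = m, n = ncol(A))
  })
}

#' K-fold cross-validation of the association model
#'
#' For every fold the test positives are zeroed out of a training copy of the
#' matrix, the similarity graphs are recomputed from that censored matrix (so
#' no label information leaks through the kernel), the model is trained on
#' the fold's training entries only, and the test positives plus test
#' negatives are scored against the original labels.
#'
#' @inheritParams make_folds
#' @param config An [ldra_control()] configuration. Per-fold training seeds
#'   are derived from `seed` so folds are decorrelated but reproducible.
#' @param seed Seed for fold construction and training (default
#'   `config$seed`).
#' @return An object of class `"ldra_cv"`: per-fold metrics (`folds`, a data
#'   frame), their mean/sd `summary`, metrics on the pooled predictions
#'   (`pooled`), and the pooled `predictions` themselves.
#' @export
ldra_cv <- function(matrix, config = ldra_control(), k = 10L,
                    mode = c("balanced", "unbalanced"), seed = config$seed) {
  mode <- match.arg(mode)
  am <- as_association_matrix(matrix)
  m <- nrow(am$A)
  folds <- make_folds(am, k = k, mode = mode, seed = seed)
  metric_names <- c("auc", "aupr", "f1", "mcc", "average_metric")
  fold_rows <- vector("list", length(folds))
  pooled_scores <- numeric(0)
  pooled_labels <- integer(0)

  for (fd in folds) {
    train_am <- am
    test_pos_lin <- pairs_to_linear(fd$test_pos, m)
    train_am$A[test_pos_lin] <- 0
    mask <- c(pairs_to_linear(fd$train_pos, m), pairs_to_linear(fd$train_neg, m))
    fold_config <- config
    fold_config$seed <- derive_seed(seed, 100L + fd$fold_id)
    neg_pool <- if (config$resample_negatives) {
      setdiff(which(as.vector(train_am$A) == 0), test_pos_lin)
    } else NULL
    fit <- tryCatch(
      train_ldra_impl(train_am, mask, fold_config, neg_pool = neg_pool),
      error = function(e) {
        stop(sprintf("fold %d: %s", fd$fold_id, conditionMessage(e)), call. = FALSE)
      })
    fw <- forward_model(fit$prep, fit$params, fit$arch, fold_config)
    scores <- score_associations(fw$lnc$emb, fw$drug$emb)
    eval_lin <- c(test_pos_lin, pairs_to_linear(fd$test_neg, m))
    eval_scores <- scores[eval_lin]
    eval_labels <- c(rep(1L, nrow(fd$test_pos)), rep(0L, nrow(fd$test_neg)))
    mt <- compute_metrics(eval_scores, eval_labels, config$threshold)
    fold_rows[[fd$fold_id + 1L]] <- data.frame(
      fold = fd$fold_id, auc = mt$auc, aupr = mt$aupr, f1 = mt$f1,
      mcc = mt$mcc, average_metric = mt$average_metric,
      n_test_pos = mt$n_pos, n_test_neg = mt$n_neg)
    pooled_scores <- c(pooled_scores, eval_scores)
    pooled_labels <- c(pooled_labels, eval_labels)
  }

  fold_df <- do.call(rbind, fold_rows)
  summ <- data.frame(
    metric = metric_names,
    mean = vapply(metric_names, function(nm) mean(fold_df[[nm]]), 0),
    sd = vapply(metric_names, function(nm) stats::sd(fold_df[[nm]]), 0),
    row.names = NULL)
  pooled <- compute_metrics(pooled_scores, pooled_labels, config$threshold)
  structure(list(folds = fold_df, summary = summ, pooled = pooled,
                 k = length(folds), mode = mode, seed = seed,
                 config = config),
            class = "ldra_cv")
}

#' @export
print.ldra_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (%s negative sampling)\n", x$k, x$mode))
  cat("Per-fold mean (sd):\n")
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf("  %-15s %.4f (%.4f)\n", x$summary$metric[i],
                x$summary$mean[i], x$summary$sd[i]))
  }
  cat("Pooled predictions:\n  ")
  print(x$pooled)
  invisible(x)
}
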