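# Independent brute-force oracles used to check the package's vectorised
# implementations. These deliberately use naive loops and definitions taken
# straight from first principles, not the package's own code paths.

# GIP similarity by explicit double loop over profile pairs.
brute_gip <- function(A, side) {
  P <- if (side == "lncrna") A else t(A)
  k <- nrow(P)
  alpha <- 1 / mean(apply(P, 1, function(r) sum(r^2)))
  G <- matrix(0, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      G[i, j] <- exp(-alpha * sum((P[i, ] - P[j, ])^2))
    }
  }
  list(alpha = alpha, G = G)
}

# Two-layer graph convolution as an explicit chain of dense products.
brute_gcn <- function(X, Ahat, W0, W1, activation) {
  H <- Ahat %*% X %*% W0
  H[H < 0] <- 0
  U <- Ahat %*% H %*% W1
  if (activation == "relu") U[U < 0] <- 0
  if (activation == "row_softmax") {
    for (i in seq_len(nrow(U))) {
      e <- exp(U[i, ] - max(U[i, ]))
      U[i, ] <- e / sum(e)
    }
  }
  U
}

# One multi-head attention layer by per-node, per-neighbour loops.
brute_gat <- function(X, mask, heads, fusion, slope) {
  k <- nrow(X)
  K <- length(heads)
  elu1 <- function(v) ifelse(v > 0, v, exp(v) - 1)
  head_out <- vector("list", K)
  for (h in seq_len(K)) {
    W <- heads[[h]]$W
    a <- heads[[h]]$a
    cdim <- ncol(W)
    Z <- X %*% W
    M <- matrix(0, k, cdim)
    for (i in seq_len(k)) {
      nb <- which(mask[i, ])
      e <- numeric(length(nb))
      for (t in seq_along(nb)) {
        cat2 <- c(Z[i, ], Z[nb[t], ])
        v <- sum(a * cat2)
        e[t] <- ifelse(v > 0, v, slope * v)
      }
      w <- exp(e - max(e))
      w <- w / sum(w)
      for (t in seq_along(nb)) M[i, ] <- M[i, ] + w[t] * Z[nb[t], ]
    }
    head_out[[h]] <- M
  }
  if (fusion == "concat") {
    do.call(cbind, lapply(head_out, elu1))
  } else {
    elu1(Reduce(`+`, head_out) / K)
  }
}

# AUC as the exhaustive pairwise comparison statistic (ties count 1/2).
brute_auc <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  tot <- 0
  for (p in sp) for (n in sn) tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(sp) * length(sn))
}

# Average precision via the precision-recall step curve at every unique
# threshold, evaluated by filtering (no cumulative trick).
brute_ap <- function(scores, labels) {
  th <- sort(unique(scores), decreasing = TRUE)
  np <- sum(labels == 1)
  prev_rec <- 0
  ap <- 0
  for (t in th) {
    sel <- scores >= t
    prec <- sum(labels[sel] == 1) / sum(sel)
    rec <- sum(labels[sel] == 1) / np
    ap <- ap + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  ap
}

brute_f1_mcc <- function(scores, labels, threshold) {
  pred <- as.integer(scores >= threshold)
  TP <- sum(pred == 1 & labels == 1); FP <- sum(pred == 1 & labels == 0)
  FN <- sum(pred == 0 & labels == 1); TN <- sum(pred == 0 & labels == 0)
  f1 <- if (2 * TP + FP + FN == 0) 0 else 2 * TP / (2 * TP + FP + FN)
  den <- sqrt(prod(c(TP + FP, TP + FN, TN + FP, TN + FN)))
  mcc <- if (den == 0) 0 else (TP * TN - FP * FN) / den
  c(f1 = f1, mcc = mcc)
}

# scikit-learn reference metrics for batches of score/label vectors, via the
# system python. Input/output through temporary JSON files.
sklearn_metrics <- function(cases, threshold = 0.5) {
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  jsonlite::write_json(lapply(cases, function(cs) {
    list(scores = cs$scores, labels = cs$labels, threshold = threshold)
  }), infile, digits = NA, auto_unbox = FALSE)
  py <- paste(
    "import json, sys",
    "from sklearn.metrics import roc_auc_score, average_precision_score, f1_score, matthews_corrcoef",
    sprintf("cases = json.load(open(%s))", deparse(infile)),
    "out = []",
    "for c in cases:",
    "    s, y, th = c['scores'], c['labels'], c['threshold'][0]",
    "    pred = [1 if v >= th else 0 for v in s]",
    "    out.append({'auc': roc_auc_score(y, s),",
    "                'aupr': average_precision_score(y, s),",
    "                'f1': f1_score(y, pred),",
    "                'mcc': matthews_corrcoef(y, pred)})",
    sprintf("json.dump(out, open(%s, 'w'))", deparse(outfile)),
    sep = "\n")
  status <- system2("python", "-", input = py, stdout = FALSE, stderr = FALSE)
  if (status != 0) stop("python/scikit-learn reference call failed")
  jsonlite::read_json(outfile, simplifyVector = TRUE)
}

# Random binary association matrix with at least one positive.
rand_am <- function(m, n, density = 0.3, seed = 1) {
  A <- withr::with_seed(seed, {
    repeat {
      A <- matrix(rbinom(m * n, 1, density), m, n)
      if (sum(A) >= 1) break
    }
    A
  })
  as_association_matrix(A)
}

# A small, fast configuration for protocol-level tests.
tiny_cfg <- function(...) {
  args <- list(epochs = 3, embedding_size = 8, gcn_hidden = 8, heads = 2,
               seed = 1)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(ldra_control, args)
}

rand_heads <- function(K, d, cdim, seed = 1) {
  withr::with_seed(seed, lapply(seq_len(K), function(h) {
    list(W = matrix(rnorm(d * cdim, sd = 0.5), d, cdim),
         a = rnorm(2 * cdim, sd = 0.5))
  }))
}
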