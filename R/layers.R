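# Encoder building blocks: normalized adjacency, graph convolution,
# graph attention. Forward passes cache intermediates for backpropagation.

relu <- function(x) pmax(x, 0)

leaky_relu <- function(x, slope) ifelse(x > 0, x, slope * x)

elu <- function(x) ifelse(x > 0, x, exp(pmin(x, 0)) - 1)

elu_grad <- function(x) ifelse(x > 0, 1, exp(pmin(x, 0)))

row_softmax <- function(x) {
  e <- exp(x - apply(x, 1, max))
  e / rowSums(e)
}

#' Symmetric-normalized adjacency with self-loops
#'
#' Computes the message-passing operator
#' \eqn{\hat{A} = \tilde{D}^{-1/2}(G + I)\tilde{D}^{-1/2}} where
#' \eqn{\tilde{D}} is the degree matrix of \eqn{G + I}. Because the added
#' self-loop puts at least 1 on every diagonal, all degrees are strictly
#' positive for any nonnegative `G`.
#'
#' @param G Square, symmetric, nonnegative similarity/adjacency matrix.
#' @return The normalized adjacency (symmetric), with attribute
#'   `self_loop_added = TRUE`.
#' @export
#' @examples
#' normalize_adjacency(matrix(c(1, 0.5, 0.5, 1), 2))
normalize_adjacency <- function(G) {
  G <- as.matrix(G)
  if (nrow(G) != ncol(G)) {
    ldra_error("ldra_contract_error", "similarity matrix must be square")
  }
  if (any(G < 0)) {
    ldra_error("ldra_contract_error", "similarity matrix must be nonnegative")
  }
  if (max(abs(G - t(G))) > 1e-8) {
    ldra_error("ldra_contract_error", "similarity matrix must be symmetric")
  }
  At <- G + diag(nrow(G))
  dinv <- 1 / sqrt(rowSums(At))
  Ahat <- At * tcrossprod(dinv)  # dinv_i * At_ij * dinv_j
  Ahat <- (Ahat + t(Ahat)) / 2
  attr(Ahat, "self_loop_added") <- TRUE
  Ahat
}

# Two-layer graph convolution with cached intermediates.
.gcn_forward <- function(X, Ahat, W0, W1, activation, drop_mask = NULL) {
  P <- Ahat %*% X
  U1 <- P %*% W0
  H1 <- relu(U1)
  if (!is.null(drop_mask)) H1 <- H1 * drop_mask
  P2 <- Ahat %*% H1
  U2 <- P2 %*% W1
  out <- switch(activation,
                row_softmax = row_softmax(U2),
                relu = relu(U2),
                identity = U2)
  if (any(!is.finite(out))) {
    ldra_error("ldra_numeric_error", "non-finite values in graph-convolution output")
  }
  list(out = out, P = P, U1 = U1, H1 = H1, P2 = P2, U2 = U2,
       activation = activation, drop_mask = drop_mask)
}

#' Two-layer graph-convolution encoder
#'
#' Propagates node features `X` through
#' `act(Ahat %*% relu(Ahat %*% X %*% W0) %*% W1)`, the standard two-layer
#' spectral graph convolution over the normalized adjacency. With
#' `activation = "row_softmax"` every output row sums to 1.
#'
#' @param X `k x d` node feature matrix.
#' @param Ahat Normalized adjacency from [normalize_adjacency()].
#' @param W0 `d x h` first-layer weights.
#' @param W1 `h x r` second-layer weights.
#' @param activation Output activation: `"row_softmax"`, `"relu"` or
#'   `"identity"`.
#' @return `k x r` feature matrix.
#' @export
gcn_encode <- function(X, Ahat, W0, W1,
                       activation = c("row_softmax", "relu", "identity")) {
  activation <- match.arg(activation)
  if (ncol(X) != nrow(W0)) {
    ldra_error("ldra_contract_error", "feature width %d does not match W0 input dim %d",
               ncol(X), nrow(W0))
  }
  if (ncol(W0) != nrow(W1)) {
    ldra_error("ldra_contract_error", "W0 output dim must match W1 input dim")
  }
  .gcn_forward(as.matrix(X), as.matrix(Ahat), W0, W1, activation)$out
}

#' Raw attention logits for one head
#'
#' For projected features `z_i = W' x_i`, the logit between nodes i and j is
#' `LeakyReLU(a' [z_i || z_j])` with `a` split into its first and second
#' halves, i.e. `LeakyReLU(a1.z_i + a2.z_j)` over all ordered pairs.
#'
#' @param X `k x d` input features.
#' @param W `d x c` per-head projection.
#' @param a Attention weight vector of length `2c`.
#' @param leaky_slope Negative slope of the LeakyReLU (default 0.2).
#' @return `k x k` matrix of attention logits.
#' @export
attention_logits <- function(X, W, a, leaky_slope = 0.2) {
  X <- as.matrix(X)
  if (ncol(X) != nrow(W)) {
    ldra_error("ldra_contract_error", "feature width %d does not match projection input dim %d",
               ncol(X), nrow(W))
  }
  if (length(a) != 2L * ncol(W)) {
    ldra_error("ldra_contract_error", "attention vector length %d must be 2 x %d",
               length(a), ncol(W))
  }
  Z <- X %*% W
  cdim <- ncol(W)
  f <- drop(Z %*% a[seq_len(cdim)])
  g <- drop(Z %*% a[cdim + seq_len(cdim)])
  leaky_relu(outer(f, rep(1, length(g))) + outer(rep(1, length(f)), g), leaky_slope)
}

#' Masked softmax normalization of attention logits
#'
#' Normalizes each row of the logit matrix over the node's neighbourhood with
#' max-subtraction stabilisation: `alpha[i, j] = exp(e[i, j]) / sum_{k in N_i}
#' exp(e[i, k])` for neighbours, 0 elsewhere. Rows over a non-empty
#' neighbourhood sum to 1.
#'
#' @param logits `k x k` logit matrix.
#' @param neighborhood `k x k` logical mask (`TRUE` = j is a neighbour of i),
#'   or `NULL` for the fully connected graph.
#' @return `k x k` matrix of attention coefficients.
#' @export
attention_normalize <- function(logits, neighborhood = NULL) {
  logits <- as.matrix(logits)
  if (is.null(neighborhood)) {
    neighborhood <- matrix(TRUE, nrow(logits), ncol(logits))
  }
  if (!all(dim(neighborhood) == dim(logits))) {
    ldra_error("ldra_contract_error", "neighborhood mask shape must match logits")
  }
  if (any(rowSums(neighborhood) == 0)) {
    ldra_error("ldra_contract_error", "every node needs at least one neighbour")
  }
  e <- logits
  e[!neighborhood] <- -Inf
  mx <- apply(e, 1, max)
  ex <- exp(e - mx)
  ex[!neighborhood] <- 0
  ex / rowSums(ex)
}

# Attention neighbourhood: full graph by default, or each node's `knn` most
# similar nodes (ties broken by smaller index) plus itself.
neighborhood_mask <- function(G, knn = NULL) {
  k <- nrow(G)
  if (is.null(knn)) return(matrix(TRUE, k, k))
  knn <- min(knn, k)
  mask <- matrix(FALSE, k, k)
  for (i in seq_len(k)) {
    ord <- order(-G[i, ], seq_len(k))
    mask[i, ord[seq_len(knn)]] <- TRUE
    mask[i, i] <- TRUE
  }
  mask
}

# One multi-head attention layer with cached intermediates.
# heads: list of list(W = d x c, a = numeric(2c)).
.gat_forward <- function(X, mask, heads, fusion, leaky_slope, drop_mask = NULL) {
  X0 <- X
  if (!is.null(drop_mask)) X <- X * drop_mask
  K <- length(heads)
  hcache <- vector("list", K)
  Ms <- vector("list", K)
  for (h in seq_len(K)) {
    W <- heads[[h]]$W
    a <- heads[[h]]$a
    cdim <- ncol(W)
    Z <- X %*% W
    f <- drop(Z %*% a[seq_len(cdim)])
    g <- drop(Z %*% a[cdim + seq_len(cdim)])
    U <- outer(f, rep(1, length(g))) + outer(rep(1, length(f)), g)
    E <- leaky_relu(U, leaky_slope)
    alpha <- attention_normalize(E, mask)
    M <- alpha %*% Z
    hcache[[h]] <- list(Z = Z, U = U, alpha = alpha)
    Ms[[h]] <- M
  }
  if (fusion == "concat") {
    out <- do.call(cbind, lapply(seq_len(K), function(h) elu(Ms[[h]])))
    Mbar <- NULL
  } else {
    Mbar <- Reduce(`+`, Ms) / K
    out <- elu(Mbar)
  }
  if (any(!is.finite(out))) {
    ldra_error("ldra_numeric_error", "non-finite values in attention-layer output")
  }
  list(out = out, X = X, X0 = X0, heads = hcache, M = Ms, Mbar = Mbar,
       fusion = fusion, mask = mask, leaky_slope = leaky_slope,
       drop_mask = drop_mask)
}

#' Multi-head graph-attention layer
#'
#' Per head, node i aggregates `sum_{j in N_i} alpha[i, j] * (W' x_j)` with
#' softmax-normalized attention coefficients; head outputs are passed through
#' an ELU and either concatenated (hidden layers, output width `K * c`) or
#' averaged before the ELU (final layer, output width `c`).
#'
#' @param X `k x d` input features.
#' @param G `k x k` similarity matrix defining the attention neighbourhood.
#' @param heads List of `K` heads, each a list with projection `W` (`d x c`)
#'   and attention vector `a` (length `2c`).
#' @param fusion `"concat"` or `"average"`.
#' @param leaky_slope LeakyReLU negative slope for the logits.
#' @param knn Optional neighbourhood size (see [ldra_control()]).
#' @param attention If `TRUE`, attach the per-head attention coefficient
#'   matrices as attribute `"attention"`.
#' @return `k x (K*c)` (concat) or `k x c` (average) feature matrix.
#' @export
gat_layer <- function(X, G, heads, fusion = c("average", "concat"),
                      leaky_slope = 0.2, knn = NULL, attention = FALSE) {
  fusion <- match.arg(fusion)
  X <- as.matrix(X)
  mask <- neighborhood_mask(as.matrix(G), knn)
  fw <- .gat_forward(X, mask, heads, fusion, leaky_slope)
  out <- fw$out
  if (attention) {
    attr(out, "attention") <- lapply(fw$heads, `[[`, "alpha")
  }
  out
}

#' Sigmoid inner-product decoder
#'
#' Scores every (lncRNA, drug) pair as the logistic function of the inner
#' product of their embeddings: `A'[i, j] = sigmoid(xl_i . xd_j)`.
#'
#' @param lnc_emb `m x c` lncRNA embedding matrix.
#' @param drug_emb `n x c` drug embedding matrix.
#' @return `m x n` score matrix with entries in (0, 1).
#' @export
#' @examples
#' score_associations(matrix(log(3), 1, 1), matrix(1, 1, 1))  # 0.75
score_associations <- function(lnc_emb, drug_emb) {
  lnc_emb <- as.matrix(lnc_emb)
  drug_emb <- as.matrix(drug_emb)
  if (ncol(lnc_emb) != ncol(drug_emb)) {
    ldra_error("ldra_contract_error", "embedding widths differ: %d vs %d",
               ncol(lnc_emb), ncol(drug_emb))
  }
  stats::plogis(tcrossprod(lnc_emb, drug_emb))
}
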