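#' Gaussian interaction-profile kernel bandwidth
#'
#' The GIP kernel compares two nodes through their binary association
#' profiles (rows of the association matrix for lncRNAs, columns for drugs).
#' Its bandwidth is the reciprocal of the mean squared Euclidean norm of the
#' profiles on the chosen side,
#' \deqn{\alpha = 1 / \left(\frac{1}{k}\sum_{i=1}^{k} \|p_i\|^2\right),}
#' so that similarity decays on the scale of a typical profile.
#'
#' @param matrix An `"assoc_matrix"` (or coercible binary matrix).
#' @param side `"lncrna"` (profiles are rows) or `"drug"` (columns).
#' @return A positive scalar bandwidth.
#' @export
#' @examples
#' am <- as_association_matrix(rbind(c(1, 0), c(0, 1), c(1, 1)))
#' gip_bandwidth(am, "lncrna")  # 1 / mean(1, 1, 2) = 3/4
gip_bandwidth <- function(matrix, side = c("lncrna", "drug")) {
  side <- match.arg(side)
  am <- as_association_matrix(matrix)
  P <- if (side == "lncrna") am$A else t(am$A)
  mean_sq <- mean(rowSums(P^2))
  if (mean_sq <= 0) {
    ldra_error("ldra_degenerate_input_error",
               "all-zero association matrix: GIP bandwidth undefined")
  }
  1 / mean_sq
}

#' Gaussian interaction-profile kernel similarity matrix
#'
#' Computes `G[i, j] = exp(-alpha * ||p_i - p_j||^2)` over all profile pairs
#' on one side of the association matrix, with `alpha` from
#' [gip_bandwidth()]. The result is symmetric with unit diagonal and entries
#' in (0, 1]. Nodes with empty profiles are allowed (their mutual similarity
#' is 1); only a globally zero matrix is rejected.
#'
#' @inheritParams gip_bandwidth
#' @return A `k x k` similarity matrix with attributes `bandwidth` and
#'   `side`.
#' @export
#' @examples
#' am <- as_association_matrix(rbind(c(1, 0), c(0, 1), c(1, 1)))
#' gip_similarity(am, "lncrna")
gip_similarity <- function(matrix, side = c("lncrna", "drug")) {
  side <- match.arg(side)
  am <- as_association_matrix(matrix)
  alpha <- gip_bandwidth(am, side)
  P <- if (side == "lncrna") am$A else t(am$A)
  sq <- rowSums(P^2)
  # ||p_i - p_j||^2 = ||p_i||^2 + ||p_j||^2 - 2 p_i . p_j
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(P)
  d2[d2 < 0] <- 0  # guard tiny negative round-off
  G <- exp(-alpha * d2)
  G <- (G + t(G)) / 2
  diag(G) <- 1
  dimnames(G) <- list(rownames(P), rownames(P))
  attr(G, "bandwidth") <- alpha
  attr(G, "side") <- side
  G
}
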