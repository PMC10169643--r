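#' Reconstruction loss of a score matrix against known associations
#'
#' Evaluated over a mask of training entries only, so held-out test entries
#' never contribute. Three variants:
#' \describe{
#'   \item{`bce`}{mean binary cross-entropy,
#'     `-mean(A*log(A') + (1-A)*log(1-A'))`, with scores clamped to
#'     `[1e-7, 1 - 1e-7]`. The default training objective.}
#'   \item{`mse`}{mean squared error `mean((A' - A)^2)`.}
#'   \item{`literal_sum`}{the signed residual sum `sum(A' - A)`. This is the
#'     reconstruction objective as originally printed for this model; being a
#'     signed sum it is unbounded below and is therefore kept as a diagnostic
#'     only — it is never optimised. It is 0 at perfect reconstruction.}
#' }
#'
#' @param scores `m x n` score matrix in (0, 1).
#' @param matrix The `"assoc_matrix"` holding the 0/1 targets.
#' @param mask Integer vector of linear (column-major) indices of the entries
#'   to evaluate; `NULL` means all entries.
#' @param variant `"bce"`, `"mse"` or `"literal_sum"`.
#' @return A scalar loss (nonnegative for `bce`/`mse`).
#' @export
#' @examples
#' am <- as_association_matrix(matrix(c(1, 0), 1))
#' reconstruction_loss(matrix(c(0.5, 0.5), 1), am, mask = 1L)  # log(2)
reconstruction_loss <- function(scores, matrix,
                                mask = NULL,
                                variant = c("bce", "mse", "literal_sum")) {
  variant <- match.arg(variant)
  am <- as_association_matrix(matrix)
  scores <- as.matrix(scores)
  if (!identical(dim(scores), dim(am$A))) {
    ldra_error("ldra_contract_error", "score/association shape mismatch")
  }
  if (is.null(mask)) mask <- seq_along(am$A)
  if (!length(mask)) ldra_error("ldra_contract_error", "empty training mask")
  p <- as.vector(scores)[mask]
  y <- as.vector(am$A)[mask]
  switch(variant,
         bce = {
           eps <- 1e-7
           pc <- pmin(pmax(p, eps), 1 - eps)
           -mean(y * log(pc) + (1 - y) * log(1 - pc))
         },
         mse = mean((p - y)^2),
         literal_sum = sum(p - y))
}

# Gradient of the training loss w.r.t. the decoder logits S (score =
# sigmoid(S)), restricted to the mask; zero elsewhere.
loss_grad_logits <- function(P, A, mask, variant) {
  dS <- matrix(0, nrow(P), ncol(P))
  p <- P[mask]
  y <- A[mask]
  n <- length(mask)
  dS[mask] <- switch(variant,
                     bce = (p - y) / n,
                     mse = 2 * (p - y) * p * (1 - p) / n)
  dS
}
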