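#' Generate a planted-block bipartite association matrix
#'
#' Rows (lncRNAs) and columns (drugs) are partitioned into `blocks`
#' contiguous groups of near-equal size (any remainder goes to the last
#' block). Entries are Bernoulli draws: probability `p_in` when the row and
#' column blocks match, `p_out` otherwise. The planted co-association blocks
#' emulate, in low-rank form, the community structure of real lncRNA-drug
#' resistance networks, giving link prediction a recoverable signal; if a
#' draw produces no positive entry it is redrawn from the same stream.
#'
#' @param m,n Numbers of lncRNAs (rows) and drugs (columns).
#' @param blocks Number of planted blocks (`>= 1`, at most `min(m, n)`).
#' @param p_in Within-block association probability.
#' @param p_out Background association probability (`0 <= p_out < p_in <= 1`).
#' @param seed Integer seed; the same parameters and seed always reproduce
#'   the same matrix.
#' @return An `"assoc_matrix"` with attributes `row_block` and `col_block`
#'   giving the planted block index of every row and column.
#' @export
#' @examples
#' am <- simulate_associations(20, 8, blocks = 2, p_in = 0.7, p_out = 0.05,
#'                             seed = 42)
#' table(attr(am, "row_block"))
simulate_associations <- function(m, n, blocks = 1L, p_in = 0.5,
                                  p_out = 0.05, seed = 1L) {
  m <- as.integer(m); n <- as.integer(n); blocks <- as.integer(blocks)
  if (m < 1L || n < 1L) ldra_error("ldra_spec_error", "m and n must be >= 1")
  if (blocks < 1L || blocks > min(m, n)) {
    ldra_error("ldra_spec_error", "blocks must satisfy 1 <= blocks <= min(m, n)")
  }
  if (!(p_out >= 0 && p_out < p_in && p_in <= 1)) {
    ldra_error("ldra_spec_error", "need 0 <= p_out < p_in <= 1")
  }
  block_sizes <- function(total) {
    s <- rep(total %/% blocks, blocks)
    s[blocks] <- s[blocks] + total %% blocks
    s
  }
  row_block <- rep(seq_len(blocks), block_sizes(m))
  col_block <- rep(seq_len(blocks), block_sizes(n))
  Pmat <- matrix(p_out, m, n)
  Pmat[outer(row_block, col_block, "==")] <- p_in
  A <- with_seed(seed, {
    repeat {
      draw <- matrix(stats::rbinom(m * n, 1L, as.vector(Pmat)), m, n)
      if (sum(draw) >= 1L) break
    }
    draw
  })
  dimnames(A) <- list(sprintf("L%03d", seq_len(m)), sprintf("D%02d", seq_len(n)))
  am <- as_association_matrix(A)
  attr(am, "row_block") <- row_block
  attr(am, "col_block") <- col_block
  am
}

#' Hold out a fraction of positive associations
#'
#' Uniformly samples `ceiling(fraction * positives)` positive entries, zeroes
#' them in a training copy of the matrix, and returns them as the held-out
#' set — the standard masked-recovery setup for link prediction benchmarks.
#'
#' @param matrix An `"assoc_matrix"`.
#' @param fraction Fraction of positives to hold out, in (0, 1). At least one
#'   positive must be held out and at least one must remain.
#' @param seed Integer seed.
#' @return A list with `train` (the censored `"assoc_matrix"`) and
#'   `held_out` (two-column index matrix of the removed positives).
#' @export
mask_associations <- function(matrix, fraction, seed = 1L) {
  am <- as_association_matrix(matrix)
  if (!(is.numeric(fraction) && fraction > 0 && fraction < 1)) {
    ldra_error("ldra_mask_error", "fraction must lie strictly in (0, 1)")
  }
  pos <- which(as.vector(am$A) == 1)
  n_hold <- ceiling(fraction * length(pos))
  if (n_hold < 1L || length(pos) - n_hold < 1L) {
    ldra_error("ldra_mask_error",
               "need at least one held-out and one remaining positive (have %d positives)",
               length(pos))
  }
  held <- with_seed(seed, sample(pos, n_hold))
  train <- am
  train$A[held] <- 0
  list(train = train, held_out = linear_to_pairs(held, nrow(am$A)))
}
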