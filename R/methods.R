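# S3 methods for fitted "ldra" objects.

#' @export
print.ldra <- function(x, ...) {
  d <- dim(x$matrix$A)
  cat("Graph-attention lncRNA-drug association model\n")
  cat(sprintf("  data: %d lncRNAs x %d drugs, %d known associations\n",
              d[1], d[2], sum(x$matrix$A)))
  cat(sprintf("  encoder: %s, %d layers, %d heads, embedding size %d\n",
              x$config$variant, x$config$layers, x$config$heads,
              x$config$embedding_size))
  if (nrow(x$history)) {
    cat(sprintf("  training: %d epochs (%s), final loss %.6f\n",
                nrow(x$history), x$config$loss,
                x$history$loss[nrow(x$history)]))
  } else {
    cat("  training: untrained (0 epochs)\n")
  }
  invisible(x)
}

#' @export
summary.ldra <- function(object, ...) {
  s <- object$scores
  known <- object$matrix$A == 1
  out <- list(
    dims = dim(object$matrix$A),
    n_pos = sum(known),
    config = object$config,
    epochs = nrow(object$history),
    first_loss = if (nrow(object$history)) object$history$loss[1] else NA_real_,
    final_loss = if (nrow(object$history)) object$history$loss[nrow(object$history)] else NA_real_,
    mean_score_known = mean(s[known]),
    mean_score_unknown = mean(s[!known])
  )
  class(out) <- "summary.ldra"
  out
}

#' @export
print.summary.ldra <- function(x, ...) {
  cat(sprintf("ldra fit: %d x %d matrix, %d positives\n",
              x$dims[1], x$dims[2], x$n_pos))
  cat(sprintf("  variant %s | layers %d | heads %d | embedding %d | lr %g\n",
              x$config$variant, x$config$layers, x$config$heads,
              x$config$embedding_size, x$config$learning_rate))
  cat(sprintf("  loss (%s): %.6f -> %.6f over %d epochs\n",
              x$config$loss, x$first_loss, x$final_loss, x$epochs))
  cat(sprintf("  mean fitted score: known pairs %.4f, other pairs %.4f\n",
              x$mean_score_known, x$mean_score_unknown))
  invisible(x)
}

#' @export
coef.ldra <- function(object, ...) object$params

#' @export
fitted.ldra <- function(object, ...) object$scores

#' @export
residuals.ldra <- function(object, ...) object$matrix$A - object$scores

#' Predict association scores or rank novel candidate pairs
#'
#' @param object A fitted `"ldra"` model.
#' @param type `"pairs"` (default) returns a ranked table of candidate pairs;
#'   `"scores"` returns the full score matrix.
#' @param top Number of top-ranked pairs to return (default all).
#' @param exclude_known Drop pairs already known positive (default `TRUE`),
#'   so the table ranks novel candidates.
#' @param ... Unused.
#' @return A data frame `lncrna, drug, score, known` sorted by descending
#'   score (ties broken by row then column index), or the score matrix.
#' @export
predict.ldra <- function(object, type = c("pairs", "scores"), top = Inf,
                         exclude_known = TRUE, ...) {
  type <- match.arg(type)
  if (type == "scores") return(object$scores)
  s <- object$scores
  m <- nrow(s); n <- ncol(s)
  i <- rep(seq_len(m), times = n)
  j <- rep(seq_len(n), each = m)
  v <- as.vector(s)
  known <- as.vector(object$matrix$A) == 1
  keep <- if (exclude_known) !known else rep(TRUE, length(v))
  ord <- order(-v[keep], i[keep], j[keep])
  if (is.finite(top)) ord <- utils::head(ord, max(0L, as.integer(top)))
  idx <- which(keep)[ord]
  data.frame(lncrna = object$matrix$lnc_ids[i[idx]],
             drug = object$matrix$drug_ids[j[idx]],
             score = v[idx],
             known = as.integer(known[idx]),
             stringsAsFactors = FALSE)
}

#' Plot the training loss curve
#'
#' @param x A fitted `"ldra"` model.
#' @param ... Passed to [plot.default()].
#' @export
plot.ldra <- function(x, ...) {
  if (!nrow(x$history)) {
    ldra_error("ldra_contract_error", "no training history to plot")
  }
  plot(x$history$epoch, x$history$loss, type = "l",
       xlab = "epoch", ylab = sprintf("%s loss", x$config$loss),
       main = "Training loss", ...)
  invisible(x)
}

#' Simulate association matrices from the fitted score matrix
#'
#' Draws Bernoulli matrices entrywise from the fitted association
#' probabilities, e.g. for parametric-bootstrap checks.
#'
#' @param object A fitted `"ldra"` model.
#' @param nsim Number of replicates.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return A list of `nsim` binary matrices.
#' @export
simulate.ldra <- function(object, nsim = 1, seed = NULL, ...) {
  draw <- function() {
    s <- object$scores
    matrix(stats::rbinom(length(s), 1, as.vector(s)), nrow(s), ncol(s),
           dimnames = dimnames(s))
  }
  if (!is.null(seed)) {
    with_seed(seed, replicate(nsim, draw(), simplify = FALSE))
  } else {
    replicate(nsim, draw(), simplify = FALSE)
  }
}
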