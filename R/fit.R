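#' Fit the graph-attention association model
#'
#' Learns lncRNA and drug embeddings from a binary association matrix and
#' scores all pairs with a sigmoid inner-product decoder. Gaussian
#' interaction-profile similarity graphs are built on both sides of the
#' matrix; node features (the similarity rows themselves) pass through a
#' two-layer graph convolution and a stack of multi-head graph-attention
#' layers. All encoder weights are trained jointly by full-batch Adam against
#' the reconstruction loss over the training entries.
#'
#' @param x An `"assoc_matrix"` (see [association_matrix()]) or a binary
#'   matrix coercible with [as_association_matrix()].
#' @param config An [ldra_control()] configuration.
#' @param train_mask Integer vector of linear (column-major) indices of the
#'   entries the loss is computed over. `NULL` (default) uses every entry.
#'   Must contain at least one positive and one negative entry.
#' @param neg_pool Optional pool of candidate-negative linear indices used
#'   when `config$resample_negatives` is `TRUE`: each epoch the negative part
#'   of the mask is redrawn from this pool to match the positive count.
#' @return An object of class `"ldra"` with components `params` (all weight
#'   tensors), `config`, `history` (per-epoch loss), `embeddings` (`lnc`,
#'   `drug`), `scores` (fitted `m x n` probability matrix), `attention`
#'   (per-layer, per-head coefficient matrices from the final forward pass),
#'   and `matrix` (the training data).
#' @seealso [predict.ldra()], [ldra_cv()], [simulate_associations()]
#' @export
#' @examples
#' am <- simulate_associations(m = 20, n = 8, blocks = 2,
#'                             p_in = 0.6, p_out = 0.05, seed = 1)
#' fit <- ldra(am, ldra_control(epochs = 5, embedding_size = 16,
#'                              gcn_hidden = 16, seed = 1))
#' fit
ldra <- function(x, config = ldra_control(), train_mask = NULL,
                 neg_pool = NULL) {
  am <- as_association_matrix(x)
  cl <- match.call()
  res <- train_ldra_impl(am, train_mask, config, neg_pool = neg_pool)
  fw <- forward_model(res$prep, res$params, res$arch, config)
  scores <- score_associations(fw$lnc$emb, fw$drug$emb)
  dimnames(scores) <- dimnames(am$A)
  structure(list(
    params = res$params,
    config = config,
    history = res$history,
    embeddings = list(lnc = fw$lnc$emb, drug = fw$drug$emb),
    scores = scores,
    attention = collect_attention(fw),
    matrix = am,
    train_mask = res$train_mask,
    call = cl
  ), class = "ldra")
}

# Graph preparation shared by training and encoding: similarity, normalized
# adjacency and attention neighbourhood for both sides.
prepare_model <- function(am, config) {
  G_l <- gip_similarity(am, "lncrna")
  G_d <- gip_similarity(am, "drug")
  list(lnc = prepare_side(G_l, config), drug = prepare_side(G_d, config))
}

forward_model <- function(prep, params, arch, config, drop = NULL) {
  list(lnc = forward_side(prep$lnc, params$lnc, arch$lnc, config, drop$lnc),
       drug = forward_side(prep$drug, params$drug, arch$drug, config, drop$drug))
}

collect_attention <- function(fw) {
  side_att <- function(s) {
    if (is.null(s$cache$gat)) return(NULL)
    lapply(s$cache$gat, function(l) lapply(l$heads, `[[`, "alpha"))
  }
  list(lnc = side_att(fw$lnc), drug = side_att(fw$drug))
}

draw_dropout <- function(arch, prep, p) {
  if (p <= 0) return(NULL)
  side <- function(a, pr) {
    k <- nrow(pr$G)
    d <- list()
    if (!is.null(a$gcn)) {
      d$gcn <- matrix(stats::rbinom(k * a$gcn$r, 1, 1 - p), k) / (1 - p)
    }
    if (length(a$gat)) {
      d$gat <- lapply(a$gat, function(l) {
        matrix(stats::rbinom(k * l$r_in, 1, 1 - p), k) / (1 - p)
      })
    }
    d
  }
  list(lnc = side(arch$lnc, prep$lnc), drug = side(arch$drug, prep$drug))
}

# Core training loop. All randomness (initialisation, dropout, per-epoch
# negative resampling) derives from config$seed.
train_ldra_impl <- function(am, train_mask, config, neg_pool = NULL) {
  A <- am$A
  m <- nrow(A); n <- ncol(A)
  if (is.null(train_mask)) train_mask <- seq_along(A)
  train_mask <- as.integer(train_mask)
  if (!length(train_mask) || any(train_mask < 1L | train_mask > length(A))) {
    ldra_error("ldra_contract_error", "train_mask must index matrix entries")
  }
  y_mask <- A[train_mask]
  if (!any(y_mask == 1) || !any(y_mask == 0)) {
    ldra_error("ldra_contract_error",
               "train_mask needs at least one positive and one negative entry")
  }
  prep <- prepare_model(am, config)
  arch <- list(lnc = side_architecture(m, config),
               drug = side_architecture(n, config))

  params <- ldra_params(m, n, config)
  state <- adam_state(params)
  losses <- numeric(config$epochs)
  pos_idx <- train_mask[y_mask == 1]

  resample <- config$resample_negatives && !is.null(neg_pool)
  with_seed(derive_seed(config$seed, 2L), {
    epoch_mask <- train_mask
    for (ep in seq_len(config$epochs)) {
      if (resample) {
        neg <- sample(neg_pool, min(length(pos_idx), length(neg_pool)))
        epoch_mask <- c(pos_idx, neg)
      }
      drop <- draw_dropout(arch, prep, config$dropout)
      fw <- forward_model(prep, params, arch, config, drop)
      S <- tcrossprod(fw$lnc$emb, fw$drug$emb)
      P <- stats::plogis(S)
      loss <- reconstruction_loss(P, am, epoch_mask, config$loss)
      if (!is.finite(loss)) {
        ldra_error("ldra_divergence_error",
                   "non-finite training loss at epoch %d", ep)
      }
      losses[ep] <- loss
      dS <- loss_grad_logits(P, A, epoch_mask, config$loss)
      dEl <- dS %*% fw$drug$emb
      dEd <- crossprod(dS, fw$lnc$emb)
      grads <- list(lnc = backward_side(fw$lnc, dEl, params$lnc, prep$lnc),
                    drug = backward_side(fw$drug, dEd, params$drug, prep$drug))
      upd <- adam_step(params, grads, state, config$learning_rate, ep,
                       config$weight_decay)
      params <- upd$params
      state <- upd$state
    }
  })
  list(params = params,
       history = data.frame(epoch = seq_len(config$epochs), loss = losses),
       prep = prep, arch = arch, train_mask = train_mask)
}

#' Encode both node sets into embeddings
#'
#' Runs the encoder (similarity, normalized adjacency, graph convolution,
#' graph attention) without training: with `params = NULL` the seed-derived
#' initial weights are used, otherwise the supplied (e.g. fitted) weights.
#'
#' @inheritParams ldra
#' @param params Optional parameter set from [ldra_params()] or a fit.
#' @param attention If `TRUE`, also return the attention coefficient maps.
#' @return A list with `lnc` (`m x c`) and `drug` (`n x c`) embedding
#'   matrices, and optionally `attention`.
#' @export
ldra_encode <- function(x, config = ldra_control(), params = NULL,
                        attention = FALSE) {
  am <- as_association_matrix(x)
  m <- nrow(am$A); n <- ncol(am$A)
  prep <- prepare_model(am, config)
  arch <- list(lnc = side_architecture(m, config),
               drug = side_architecture(n, config))
  if (is.null(params)) params <- ldra_params(m, n, config)
  fw <- forward_model(prep, params, arch, config)
  out <- list(lnc = fw$lnc$emb, drug = fw$drug$emb)
  if (attention) out$attention <- collect_attention(fw)
  out
}

#' Save or load a model checkpoint
#'
#' The checkpoint is a single RDS file holding all parameter tensors, the
#' full configuration and the data dimensions; loading re-validates parameter
#' shapes against the stored configuration.
#'
#' @param fit A fitted `"ldra"` object.
#' @param path Checkpoint file path.
#' @return `save_ldra` returns `path` invisibly; `load_ldra` returns a list
#'   with `params`, `config`, `dims` and the identifier vectors.
#' @export
save_ldra <- function(fit, path) {
  stopifnot(inherits(fit, "ldra"))
  saveRDS(list(params = fit$params, config = fit$config,
               dims = dim(fit$matrix$A),
               lnc_ids = fit$matrix$lnc_ids,
               drug_ids = fit$matrix$drug_ids,
               version = as.character(utils::packageVersion("ldra"))),
          path)
  invisible(path)
}

#' @rdname save_ldra
#' @export
load_ldra <- function(path) {
  ck <- readRDS(path)
  ref <- ldra_params(ck$dims[1], ck$dims[2], ck$config)
  same_shape <- function(a, b) {
    if (is.numeric(a)) return(is.numeric(b) && identical(dim(a), dim(b)) &&
                                length(a) == length(b))
    is.list(b) && identical(names(a), names(b)) &&
      all(mapply(same_shape, a, b))
  }
  if (!same_shape(ref, ck$params)) {
    ldra_error("ldra_checkpoint_error",
               "checkpoint parameter shapes do not match its configuration")
  }
  ck
}
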