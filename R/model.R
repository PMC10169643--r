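# Model assembly: per-side architectures, Glorot initialisation, full
# forward pass, hand-derived backpropagation, and the Adam optimiser.

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

glorot_vec <- function(len) {
  lim <- sqrt(6 / (len + 1))
  stats::runif(len, -lim, lim)
}

# Architecture of one side (k nodes): which stages exist and their widths.
# The convolution stage is fixed at two layers; `layers - 2` attention layers
# follow. Hidden attention layers concatenate heads (per-head width
# c_total / K), the final one averages them (per-head width c_total).
side_architecture <- function(k, config) {
  r <- config$gcn_hidden
  c_total <- config$embedding_size
  K <- config$heads
  n_gat <- max(0L, config$layers - 2L)
  arch <- list(gcn = NULL, gat = list(), proj = NULL)
  use_gcn <- config$variant %in% c("full", "gcn_only")
  use_gat <- config$variant %in% c("full", "gat_only")
  if (use_gcn) arch$gcn <- list(d_in = k, r = r)
  if (use_gat) {
    if (config$variant == "gat_only") n_gat <- max(1L, n_gat)
    if (n_gat >= 1L) {
      first_in <- if (use_gcn) r else k
      for (l in seq_len(n_gat)) {
        fusion <- if (l < n_gat) "concat" else "average"
        cdim <- if (fusion == "concat") c_total %/% K else c_total
        r_in <- if (l == 1L) first_in else c_total
        arch$gat[[l]] <- list(r_in = r_in, c = cdim, fusion = fusion, K = K)
      }
    }
  }
  gat_out <- if (length(arch$gat)) c_total else NULL
  if (use_gcn && !length(arch$gat)) arch$proj <- c(r, c_total)
  arch$out_width <- gat_out %||% c_total
  arch
}

init_side_params <- function(arch) {
  p <- list()
  if (!is.null(arch$gcn)) {
    p$gcn <- list(W0 = glorot(arch$gcn$d_in, arch$gcn$r),
                  W1 = glorot(arch$gcn$r, arch$gcn$r))
  }
  if (length(arch$gat)) {
    p$gat <- lapply(arch$gat, function(l) {
      list(heads = lapply(seq_len(l$K), function(h) {
        list(W = glorot(l$r_in, l$c), a = glorot_vec(2L * l$c))
      }))
    })
  }
  if (!is.null(arch$proj)) {
    p$proj <- glorot(arch$proj[1], arch$proj[2])
  }
  p
}

#' Initialise model parameters
#'
#' Draws all encoder weights (Glorot-uniform) for both node sets from the
#' configuration seed. Parameter shapes are a function of `(m, n, config)`
#' only.
#'
#' @param m,n Numbers of lncRNAs and drugs.
#' @param config An [ldra_control()] configuration.
#' @return Nested list with components `lnc` and `drug`.
#' @export
ldra_params <- function(m, n, config = ldra_control()) {
  arch_l <- side_architecture(m, config)
  arch_d <- side_architecture(n, config)
  with_seed(derive_seed(config$seed, 1L), {
    list(lnc = init_side_params(arch_l), drug = init_side_params(arch_d))
  })
}

# Resolve the configured neighbourhood size for a k-node graph: "auto" is
# ceiling(sqrt(k)), "full" means complete-graph attention (NULL mask).
resolve_knn <- function(knn, k) {
  if (is.character(knn)) {
    if (knn == "full") return(NULL)
    return(as.integer(ceiling(sqrt(k))))
  }
  knn
}

# Precompute everything about the graphs that is constant across epochs.
prepare_side <- function(G, config) {
  Ahat <- normalize_adjacency(G)
  list(G = unclass(G), Ahat = Ahat,
       mask = neighborhood_mask(G, resolve_knn(config$knn, nrow(G))))
}

# Forward pass of one side; X (initial node features) is the similarity
# matrix itself. Returns the embedding plus caches for backprop.
forward_side <- function(prep, params, arch, config, drop = NULL) {
  cur <- prep$G
  cache <- list()
  if (!is.null(params$gcn)) {
    cache$gcn <- .gcn_forward(cur, prep$Ahat, params$gcn$W0, params$gcn$W1,
                              config$activation_out, drop_mask = drop$gcn)
    cur <- cache$gcn$out
  }
  if (!is.null(params$gat)) {
    cache$gat <- vector("list", length(params$gat))
    for (l in seq_along(params$gat)) {
      cache$gat[[l]] <- .gat_forward(cur, prep$mask, params$gat[[l]]$heads,
                                     arch$gat[[l]]$fusion, config$leaky_slope,
                                     drop_mask = drop$gat[[l]])
      cur <- cache$gat[[l]]$out
    }
  }
  if (!is.null(params$proj)) {
    cache$proj_in <- cur
    cur <- cur %*% params$proj
  }
  list(emb = cur, cache = cache)
}

backward_gat_layer <- function(cache, dOut, heads_params) {
  K <- length(heads_params)
  X <- cache$X
  slope <- cache$leaky_slope
  if (cache$fusion == "concat") {
    cdim <- ncol(cache$M[[1]])
    dMs <- lapply(seq_len(K), function(h) {
      block <- dOut[, (h - 1L) * cdim + seq_len(cdim), drop = FALSE]
      block * elu_grad(cache$M[[h]])
    })
  } else {
    dMbar <- dOut * elu_grad(cache$Mbar)
    dMs <- rep(list(dMbar / K), K)
  }
  dX <- matrix(0, nrow(X), ncol(X))
  gheads <- vector("list", K)
  for (h in seq_len(K)) {
    hc <- cache$heads[[h]]
    W <- heads_params[[h]]$W
    a <- heads_params[[h]]$a
    cdim <- ncol(W)
    a1 <- a[seq_len(cdim)]
    a2 <- a[cdim + seq_len(cdim)]
    dM <- dMs[[h]]
    dalpha <- tcrossprod(dM, hc$Z)
    dZ <- crossprod(hc$alpha, dM)
    srow <- rowSums(hc$alpha * dalpha)
    dE <- hc$alpha * (dalpha - srow)
    dU <- dE * ifelse(hc$U > 0, 1, slope)
    df <- rowSums(dU)
    dg <- colSums(dU)
    dZ <- dZ + outer(df, a1) + outer(dg, a2)
    da <- c(drop(crossprod(hc$Z, df)), drop(crossprod(hc$Z, dg)))
    gheads[[h]] <- list(W = crossprod(X, dZ), a = da)
    dX <- dX + tcrossprod(dZ, W)
  }
  if (!is.null(cache$drop_mask)) dX <- dX * cache$drop_mask
  list(heads = gheads, dX = dX)
}

backward_gcn <- function(cache, dOut, W0, W1, Ahat) {
  dU2 <- switch(cache$activation,
                row_softmax = cache$out * (dOut - rowSums(cache$out * dOut)),
                relu = dOut * (cache$U2 > 0),
                identity = dOut)
  dW1 <- crossprod(cache$P2, dU2)
  dP2 <- tcrossprod(dU2, W1)
  dH1 <- Ahat %*% dP2  # Ahat symmetric
  if (!is.null(cache$drop_mask)) dH1 <- dH1 * cache$drop_mask
  dU1 <- dH1 * (cache$U1 > 0)
  dW0 <- crossprod(cache$P, dU1)
  list(W0 = dW0, W1 = dW1)
}

backward_side <- function(fw, dEmb, params, prep) {
  g <- list()
  cur <- dEmb
  if (!is.null(params$proj)) {
    g$proj <- crossprod(fw$cache$proj_in, cur)
    cur <- tcrossprod(cur, params$proj)
  }
  if (!is.null(params$gat)) {
    g$gat <- vector("list", length(params$gat))
    for (l in rev(seq_along(params$gat))) {
      bl <- backward_gat_layer(fw$cache$gat[[l]], cur, params$gat[[l]]$heads)
      g$gat[[l]] <- list(heads = bl$heads)
      cur <- bl$dX
    }
  }
  if (!is.null(params$gcn)) {
    g$gcn <- backward_gcn(fw$cache$gcn, cur, params$gcn$W0, params$gcn$W1,
                          prep$Ahat)
  }
  # reorder to mirror the parameter structure
  g[names(params)]
}

# ---- Adam ------------------------------------------------------------------

adam_state <- function(params) {
  if (is.numeric(params)) return(list(m = params * 0, v = params * 0))
  lapply(params, adam_state)
}

adam_step <- function(params, grads, state, lr, t, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (is.numeric(params)) {
    g <- grads
    if (weight_decay > 0) g <- g + weight_decay * params
    state$m <- beta1 * state$m + (1 - beta1) * g
    state$v <- beta2 * state$v + (1 - beta2) * g^2
    mhat <- state$m / (1 - beta1^t)
    vhat <- state$v / (1 - beta2^t)
    params <- params - lr * mhat / (sqrt(vhat) + eps)
    return(list(params = params, state = state))
  }
  for (nm in names(params)) {
    res <- adam_step(params[[nm]], grads[[nm]], state[[nm]], lr, t,
                     weight_decay, beta1, beta2, eps)
    params[[nm]] <- res$params
    state[[nm]] <- res$state
  }
  list(params = params, state = state)
}
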