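#' Training configuration for the association model
#'
#' Collects every tunable of the encoder-decoder and its optimisation into a
#' validated list, in the spirit of [glm.control()]. Defaults follow the
#' published parameter analysis for this model family: learning rate 1e-4,
#' 3 message-passing layers, 8 attention heads, embedding size 200.
#'
#' @param learning_rate Adam step size. Default `1e-4`.
#' @param epochs Number of full-batch training epochs. `0` returns the
#'   initialised, untrained model. Default `400`.
#' @param layers Total message-passing depth. The graph-convolution stage is
#'   always two layers; `layers - 2` graph-attention layers follow (so the
#'   default `3` gives a single attention layer). With `layers = 2` the
#'   convolution output is linearly projected to the embedding size.
#' @param heads Number of attention heads per attention layer. Default `8`.
#' @param embedding_size Width of the final node embeddings. Must be divisible
#'   by `heads` whenever more than one attention layer is stacked (hidden
#'   attention layers concatenate their heads). Default `200`.
#' @param gcn_hidden Width of the graph-convolution output fed to the
#'   attention stage. Default equals `embedding_size`.
#' @param loss Training objective: `"bce"` (binary cross-entropy, default) or
#'   `"mse"`. See [reconstruction_loss()] for the diagnostic `"literal_sum"`
#'   variant, which is never optimised.
#' @param variant Encoder variant: `"full"` (convolution then attention,
#'   default), `"gcn_only"`, or `"gat_only"` (attention applied directly to
#'   the similarity rows). The ablation variants share the full model's
#'   similarity inputs.
#' @param knn Neighbourhood size for the attention layers: each node attends
#'   to its `knn` most similar nodes plus itself. The default `"auto"` uses
#'   `ceiling(sqrt(k))` per graph (`k` nodes); `"full"` or `Inf` attends over
#'   the complete graph. Attention over the complete graph is degenerate for
#'   this logit form — see the methods vignette — so a sparsified
#'   neighbourhood is the default.
#' @param seed Integer seed governing every random draw of a fit.
#' @param activation_out Output activation of the convolution stage:
#'   `"identity"` (default, the feature-extractor convention of graph
#'   auto-encoders), `"relu"`, or `"row_softmax"` (which normalises every
#'   feature row to the simplex; with wide feature matrices this squashes
#'   node features towards uniform and starves the attention stage — see the
#'   methods vignette).
#' @param threshold Score cut-off used for the thresholded classification
#'   metrics (F1, MCC). Default `0.5`, the natural operating point of a
#'   sigmoid decoder.
#' @param leaky_slope Negative slope of the LeakyReLU inside the attention
#'   logits. Default `0.2`.
#' @param weight_decay L2 penalty coefficient added to gradients. Default `0`.
#' @param dropout Dropout probability applied to the convolution hidden layer
#'   and attention-layer inputs during training. Default `0`.
#' @param resample_negatives If `TRUE`, balanced training negatives are
#'   redrawn from the candidate pool every epoch instead of once per fold.
#'   Default `FALSE`.
#' @param ... Unused; supplying an unknown argument is an error that lists the
#'   valid keys.
#'
#' @return A list of class `"ldra_control"`.
#' @seealso [ldra()], [ldra_cv()], [read_ldra_control()]
#' @export
#' @examples
#' ldra_control(epochs = 50, seed = 7)
ldra_control <- function(learning_rate = 1e-4,
                         epochs = 400L,
                         layers = 3L,
                         heads = 8L,
                         embedding_size = 200L,
                         gcn_hidden = embedding_size,
                         loss = c("bce", "mse"),
                         variant = c("full", "gcn_only", "gat_only"),
                         knn = "auto",
                         seed = 1L,
                         activation_out = c("identity", "relu", "row_softmax"),
                         threshold = 0.5,
                         leaky_slope = 0.2,
                         weight_decay = 0,
                         dropout = 0,
                         resample_negatives = FALSE,
                         ...) {
  extra <- list(...)
  if (length(extra)) {
    valid <- setdiff(names(formals(ldra_control)), "...")
    ldra_error("ldra_config_error",
               "unknown configuration key(s): %s\nvalid keys: %s",
               paste(names(extra), collapse = ", "),
               paste(valid, collapse = ", "))
  }
  loss <- match.arg(loss)
  variant <- match.arg(variant)
  activation_out <- match.arg(activation_out)

  chk <- function(ok, msg, ...) if (!isTRUE(ok)) ldra_error("ldra_config_error", msg, ...)
  chk(is.numeric(learning_rate) && learning_rate > 0, "learning_rate must be positive")
  epochs <- as.integer(epochs)
  chk(!is.na(epochs) && epochs >= 0L, "epochs must be a nonnegative integer")
  layers <- as.integer(layers)
  chk(!is.na(layers) && layers >= 2L, "layers must be an integer >= 2")
  heads <- as.integer(heads)
  chk(!is.na(heads) && heads >= 1L, "heads must be an integer >= 1")
  embedding_size <- as.integer(embedding_size)
  chk(!is.na(embedding_size) && embedding_size >= 1L, "embedding_size must be >= 1")
  gcn_hidden <- as.integer(gcn_hidden)
  chk(!is.na(gcn_hidden) && gcn_hidden >= 1L, "gcn_hidden must be >= 1")
  n_gat <- max(0L, layers - 2L)
  if (n_gat > 1L && embedding_size %% heads != 0L) {
    ldra_error("ldra_config_error",
               "embedding_size (%d) must be divisible by heads (%d) when concatenating attention layers are stacked",
               embedding_size, heads)
  }
  if (is.null(knn) || (is.character(knn) && knn %in% c("auto", "full"))) {
    knn <- knn %||% "auto"
  } else if (is.numeric(knn)) {
    if (is.infinite(knn)) {
      knn <- "full"
    } else {
      knn <- as.integer(knn)
      chk(!is.na(knn) && knn >= 1L, "knn must be 'auto', 'full', or an integer >= 1")
    }
  } else {
    ldra_error("ldra_config_error", "knn must be 'auto', 'full', or an integer >= 1")
  }
  seed <- as.integer(seed)
  chk(!is.na(seed), "seed must be an integer")
  chk(is.numeric(threshold) && threshold > 0 && threshold < 1, "threshold must lie in (0, 1)")
  chk(is.numeric(leaky_slope) && leaky_slope >= 0, "leaky_slope must be nonnegative")
  chk(is.numeric(weight_decay) && weight_decay >= 0, "weight_decay must be nonnegative")
  chk(is.numeric(dropout) && dropout >= 0 && dropout < 1, "dropout must lie in [0, 1)")

  structure(list(
    learning_rate = learning_rate, epochs = epochs, layers = layers,
    heads = heads, embedding_size = embedding_size, gcn_hidden = gcn_hidden,
    loss = loss, variant = variant, knn = knn, seed = seed,
    activation_out = activation_out, threshold = threshold,
    leaky_slope = leaky_slope, weight_decay = weight_decay,
    dropout = dropout, resample_negatives = isTRUE(resample_negatives)
  ), class = "ldra_control")
}

#' Read a training configuration from a YAML file with overrides
#'
#' Resolution order is defaults, then file values, then `overrides`, matching
#' the usual config-file-plus-command-line-flags precedence.
#'
#' @param path Path to a YAML file whose keys are [ldra_control()] arguments,
#'   or `NULL` for defaults only.
#' @param overrides Named list applied on top of the file values.
#' @return A validated `"ldra_control"` list.
#' @export
read_ldra_control <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) {
      ldra_error("ldra_config_error", "config file not found: %s", path)
    }
    vals <- yaml::read_yaml(path)
    if (is.null(vals)) vals <- list()
    if (!is.list(vals)) {
      ldra_error("ldra_config_error", "config file must contain a YAML mapping: %s", path)
    }
  }
  keep <- names(overrides)[!vapply(overrides, is.null, logical(1))]
  vals[keep] <- overrides[keep]
  do.call(ldra_control, vals)
}
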