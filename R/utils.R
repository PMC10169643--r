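# Internal helpers shared across the package.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

# Derive a per-component seed from a base seed; stays inside 32-bit range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483647)
}

ldra_error <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "ldra_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

# Convert (row, col) pair matrix to linear (column-major) indices and back.
pairs_to_linear <- function(pairs, m) {
  as.integer(pairs[, 1] + (pairs[, 2] - 1L) * m)
}

linear_to_pairs <- function(idx, m) {
  idx <- as.integer(idx)
  cbind(row = ((idx - 1L) %% m) + 1L, col = ((idx - 1L) %/% m) + 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
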