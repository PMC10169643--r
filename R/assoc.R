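#' Read an lncRNA-drug association edge list
#'
#' Parses delimited text with columns `lncrna_id, drug_id[, label]`. A missing
#' label means a known (positive) association; an explicit `0` records a known
#' negative, which the cross-validation sampler prefers over merely unobserved
#' pairs. Duplicate rows are collapsed; duplicates that disagree on the label
#' are a data-integrity error.
#'
#' @param path Path to a delimited text file (or a character vector of lines
#'   via `text`).
#' @param delimiter Field separator. `NULL` (default) autodetects tab versus
#'   comma from the first non-empty line.
#' @param header If `TRUE`, the first non-empty line is discarded.
#' @param text Optional character vector of lines, used instead of `path`.
#' @return A data frame with columns `lncrna`, `drug`, `label` (0/1), one row
#'   per unique pair, in first-appearance order.
#' @seealso [association_matrix()]
#' @export
#' @examples
#' read_associations(text = c("L1,D1", "L2,D1,1", "L2,D2,0"))
read_associations <- function(path = NULL, delimiter = NULL, header = FALSE,
                              text = NULL) {
  lines <- if (!is.null(text)) text else {
    if (is.null(path) || !file.exists(path)) {
      ldra_error("ldra_parse_error", "edge list not readable: %s",
                 if (is.null(path)) "<missing path>" else path)
    }
    readLines(path, warn = FALSE)
  }
  keep <- which(nzchar(trimws(lines)))
  if (!length(keep)) ldra_error("ldra_parse_error", "edge list is empty")
  if (is.null(delimiter)) {
    delimiter <- if (grepl("\t", lines[keep[1]], fixed = TRUE)) "\t" else ","
  }
  if (isTRUE(header)) keep <- keep[-1]
  if (!length(keep)) ldra_error("ldra_parse_error", "edge list has a header but no data rows")

  fields <- strsplit(lines[keep], delimiter, fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 2L | nf > 3L)
  if (length(bad)) {
    ldra_error("ldra_parse_error", "malformed row at line %d: expected 2 or 3 fields, got %d",
               keep[bad[1]], nf[bad[1]])
  }
  lnc <- trimws(vapply(fields, `[[`, "", 1L))
  drug <- trimws(vapply(fields, `[[`, "", 2L))
  lab_chr <- trimws(vapply(fields, function(f) if (length(f) >= 3L) f[[3L]] else "1", ""))
  empty <- which(!nzchar(lnc) | !nzchar(drug))
  if (length(empty)) {
    ldra_error("ldra_parse_error", "empty identifier at line %d", keep[empty[1]])
  }
  badlab <- which(!lab_chr %in% c("0", "1"))
  if (length(badlab)) {
    ldra_error("ldra_parse_error", "label must be 0 or 1 at line %d (got '%s')",
               keep[badlab[1]], lab_chr[badlab[1]])
  }
  label <- as.integer(lab_chr)

  key <- paste(lnc, drug, sep = "\r")
  split_lab <- split(label, factor(key, levels = unique(key)))
  conflict <- names(split_lab)[vapply(split_lab, function(x) length(unique(x)) > 1L, logical(1))]
  if (length(conflict)) {
    pair <- strsplit(conflict[1], "\r", fixed = TRUE)[[1]]
    ldra_error("ldra_integrity_error",
               "conflicting labels for duplicated pair (%s, %s)", pair[1], pair[2])
  }
  first <- !duplicated(key)
  data.frame(lncrna = lnc[first], drug = drug[first], label = label[first],
             stringsAsFactors = FALSE)
}

#' Build an indexed binary association matrix from parsed records
#'
#' Rows (lncRNAs) and columns (drugs) are ordered by first appearance in the
#' records; `A[i, j] = 1` iff a positive record links them. Explicitly
#' 0-labelled records are retained separately as known negatives for the
#' negative sampler; all other zero entries are treated as unknown candidates.
#'
#' @param records Data frame as returned by [read_associations()] (columns
#'   `lncrna`, `drug`, optional `label`; a missing label column means all
#'   positive).
#' @return An object of class `"assoc_matrix"`: a list with the binary matrix
#'   `A` (with identifier dimnames), `lnc_ids`, `drug_ids`, and `known_neg`
#'   (a two-column index matrix of known-negative pairs).
#' @export
#' @examples
#' am <- association_matrix(read_associations(text = c("L1,D1", "L1,D2", "L2,D1")))
#' am$A
association_matrix <- function(records) {
  if (!is.data.frame(records) || !all(c("lncrna", "drug") %in% names(records))) {
    ldra_error("ldra_contract_error", "records must have columns 'lncrna' and 'drug'")
  }
  if (is.null(records$label)) records$label <- 1L
  key <- paste(records$lncrna, records$drug, sep = "\r")
  split_lab <- split(records$label, factor(key, levels = unique(key)))
  if (any(vapply(split_lab, function(x) length(unique(x)) > 1L, logical(1)))) {
    ldra_error("ldra_integrity_error", "conflicting labels among records")
  }
  records <- records[!duplicated(key), , drop = FALSE]
  if (sum(records$label == 1L) < 1L) {
    ldra_error("ldra_empty_input_error", "no positive association records")
  }
  lnc_ids <- unique(records$lncrna)
  drug_ids <- unique(records$drug)
  m <- length(lnc_ids)
  n <- length(drug_ids)
  A <- matrix(0, m, n, dimnames = list(lnc_ids, drug_ids))
  i <- match(records$lncrna, lnc_ids)
  j <- match(records$drug, drug_ids)
  pos <- records$label == 1L
  A[cbind(i[pos], j[pos])] <- 1
  known_neg <- cbind(row = i[!pos], col = j[!pos])
  structure(list(A = A, lnc_ids = lnc_ids, drug_ids = drug_ids,
                 known_neg = known_neg),
            class = "assoc_matrix")
}

#' Coerce a binary matrix to an `assoc_matrix`
#'
#' @param A Numeric matrix over \{0, 1\}. Dimnames are used as identifiers when
#'   present, otherwise `L<i>` / `D<j>` names are generated.
#' @param known_neg Optional two-column index matrix of known-negative pairs.
#' @return An `"assoc_matrix"` object.
#' @export
as_association_matrix <- function(A, known_neg = NULL) {
  if (inherits(A, "assoc_matrix")) return(A)
  A <- as.matrix(A)
  if (!all(A %in% c(0, 1))) {
    ldra_error("ldra_contract_error", "association matrix entries must be 0 or 1")
  }
  if (nrow(A) < 1L || ncol(A) < 1L) {
    ldra_error("ldra_contract_error", "association matrix must be at least 1 x 1")
  }
  lnc_ids <- rownames(A) %||% sprintf("L%d", seq_len(nrow(A)))
  drug_ids <- colnames(A) %||% sprintf("D%d", seq_len(ncol(A)))
  dimnames(A) <- list(lnc_ids, drug_ids)
  structure(list(A = A, lnc_ids = lnc_ids, drug_ids = drug_ids,
                 known_neg = known_neg %||% cbind(row = integer(0), col = integer(0))),
            class = "assoc_matrix")
}

#' @export
print.assoc_matrix <- function(x, ...) {
  cat(sprintf("lncRNA-drug association matrix: %d lncRNAs x %d drugs, %d known associations",
              nrow(x$A), ncol(x$A), sum(x$A)), "\n")
  if (nrow(x$known_neg)) {
    cat(sprintf("  plus %d known-negative pairs\n", nrow(x$known_neg)))
  }
  invisible(x)
}

#' @export
dim.assoc_matrix <- function(x) dim(x$A)

#' Write a ranked prediction table
#'
#' One row per (lncRNA, drug) pair with the predicted score and the known
#' label, sorted by descending score; ties are broken by (row index, column
#' index). Scores are serialised with 8 significant digits.
#'
#' @param scores `m x n` numeric score matrix.
#' @param matrix The `"assoc_matrix"` the scores refer to.
#' @param path Output file path (tab-separated, with header).
#' @return Invisibly, the data frame that was written.
#' @export
write_predictions <- function(scores, matrix, path) {
  matrix <- as_association_matrix(matrix)
  scores <- as.matrix(scores)
  if (!identical(dim(scores), dim(matrix$A))) {
    ldra_error("ldra_contract_error",
               "score matrix is %d x %d but association matrix is %d x %d",
               nrow(scores), ncol(scores), nrow(matrix$A), ncol(matrix$A))
  }
  m <- nrow(scores); n <- ncol(scores)
  i <- rep(seq_len(m), times = n)
  j <- rep(seq_len(n), each = m)
  s <- as.vector(scores)
  ord <- order(-s, i, j)
  out <- data.frame(lncrna = matrix$lnc_ids[i[ord]],
                    drug = matrix$drug_ids[j[ord]],
                    score = s[ord],
                    known = as.integer(as.vector(matrix$A)[ord]),
                    stringsAsFactors = FALSE)
  txt <- out
  txt$score <- sprintf("%.8g", out$score)
  utils::write.table(txt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
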