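#' Construct an expression matrix
#'
#' The package-wide container for single-cell expression data: a dense numeric
#' matrix with cells in rows and genes in columns, carrying unique cell ids and
#' gene names. Values are expected on a log scale (e.g. logTPM / logRPKM) and
#' must be non-negative and finite; dropout zeros are ordinary zero entries.
#'
#' @param values Numeric matrix, cells x genes.
#' @param gene_names Character vector of unique gene names (default: column
#'   names of `values`, or `gene1..geneN`).
#' @param cell_ids Character vector of unique cell identifiers (default: row
#'   names of `values`, or `cell1..cellM`).
#' @param log1p If `TRUE`, apply `log1p()` to the values at construction.
#'   Off by default: inputs are assumed already log-transformed.
#' @return An object of class `expression_matrix` (a classed numeric matrix).
#' @examples
#' x <- expression_matrix(matrix(runif(6), 2, 3))
#' dim(x)
#' @export
expression_matrix <- function(values, gene_names = NULL, cell_ids = NULL,
                              log1p = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_names)) gene_names <- colnames(values)
  if (is.null(cell_ids)) cell_ids <- rownames(values)
  if (is.null(gene_names)) gene_names <- paste0("gene", seq_len(ncol(values)))
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(nrow(values)))
  gene_names <- trimws(as.character(gene_names))
  cell_ids <- trimws(as.character(cell_ids))
  if (log1p) values <- log1p(values)
  dimnames(values) <- list(cell_ids, gene_names)
  class(values) <- c("expression_matrix", "matrix", "array")
  validate_expression_matrix(values)
  values
}

#' Validate an expression matrix
#'
#' Checks the container invariants: at least one cell and one gene, all values
#' finite and non-negative, and no duplicated gene names or cell ids after
#' whitespace canonicalization.
#'
#' @param x An `expression_matrix`.
#' @return `x`, invisibly, if valid; otherwise an error.
#' @export
validate_expression_matrix <- function(x) {
  if (nrow(x) < 1L || ncol(x) < 1L) {
    stop_scdrivers("expression matrix must have at least 1 cell and 1 gene")
  }
  if (anyNA(x) || any(!is.finite(unclass(x)))) {
    stop_scdrivers("expression matrix contains non-finite values")
  }
  if (any(unclass(x) < 0)) {
    bad <- which(unclass(x) < 0, arr.ind = TRUE)[1L, ]
    stop_scdrivers(
      "negative expression value at cell '", rownames(x)[bad[1L]],
      "', gene '", colnames(x)[bad[2L]], "' (log-expression must be >= 0)")
  }
  dup <- unique(colnames(x)[duplicated(colnames(x))])
  if (length(dup) > 0L) {
    stop_scdrivers("duplicate gene name(s): ", paste(dup, collapse = ", "))
  }
  dup <- unique(rownames(x)[duplicated(rownames(x))])
  if (length(dup) > 0L) {
    stop_scdrivers("duplicate cell id(s): ", paste(dup, collapse = ", "))
  }
  invisible(x)
}

#' @export
`[.expression_matrix` <- function(x, i, j, drop = FALSE) {
  y <- unclass(x)
  out <- if (missing(i) && missing(j)) {
    y
  } else if (missing(i)) {
    y[, j, drop = drop]
  } else if (missing(j)) {
    y[i, , drop = drop]
  } else {
    y[i, j, drop = drop]
  }
  if (is.matrix(out)) class(out) <- c("expression_matrix", "matrix", "array")
  out
}

#' Gene names of an expression matrix
#' @param x An `expression_matrix`.
#' @return Character vector of gene names.
#' @export
gene_names <- function(x) colnames(x)

#' Cell ids of an expression matrix
#' @param x An `expression_matrix`.
#' @return Character vector of cell ids.
#' @export
cell_ids <- function(x) rownames(x)

#' Number of cells / genes
#' @param x An `expression_matrix`.
#' @return Integer count.
#' @export
n_cells <- function(x) nrow(x)

#' @rdname n_cells
#' @export
n_genes <- function(x) ncol(x)

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d cells x %d genes\n", nrow(x), ncol(x)))
  cat(sprintf("  values in [%.3g, %.3g], %.1f%% zeros\n",
              min(x), max(x), 100 * mean(unclass(x) == 0)))
  invisible(x)
}

#' @export
as.matrix.expression_matrix <- function(x, ...) {
  class(x) <- NULL
  x
}

#' Per-cell group annotation
#'
#' Aligns a label per cell with an expression matrix; used for the two-group
#' (tumor vs non-tumor) differential expression stage and for evaluation
#' against known or planted labels.
#'
#' @param cell_ids Character vector of cell ids.
#' @param group Vector of labels (factor, character or integer), one per cell.
#' @return A data.frame of class `cell_annotation` with columns `cell_id`,
#'   `group`.
#' @export
cell_annotation <- function(cell_ids, group) {
  cell_ids <- trimws(as.character(cell_ids))
  if (length(cell_ids) != length(group)) {
    stop_scdrivers("cell_ids and group lengths differ (",
                   length(cell_ids), " vs ", length(group), ")")
  }
  if (anyDuplicated(cell_ids)) stop_scdrivers("duplicate cell ids in annotation")
  out <- data.frame(cell_id = cell_ids, group = group,
                    stringsAsFactors = FALSE)
  class(out) <- c("cell_annotation", "data.frame")
  out
}

# Align an annotation with a matrix; returns the group vector in matrix order.
align_annotation <- function(x, annotation) {
  if (inherits(annotation, "cell_annotation") || is.data.frame(annotation)) {
    idx <- match(rownames(x), annotation$cell_id)
    if (anyNA(idx)) {
      stop_scdrivers("annotation is missing cells: ",
                     paste(utils::head(rownames(x)[is.na(idx)], 5),
                           collapse = ", "))
    }
    annotation$group[idx]
  } else {
    if (length(annotation) != nrow(x)) {
      stop_scdrivers("group vector length (", length(annotation),
                     ") does not match cell count (", nrow(x), ")")
    }
    annotation
  }
}
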