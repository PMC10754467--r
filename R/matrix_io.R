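# Readers and writers for expression matrices and result tables.
#
# Internally everything is cells x genes; files may store either orientation
# and are normalized at read time via the `orientation` flag.

#' Read a dense delimited expression matrix
#'
#' Reads a TSV/CSV matrix with a header row and a leading name column. The
#' file may store genes in rows (the common expression-table layout) or cells
#' in rows; either way the result is cells x genes.
#'
#' @param path Path to the file.
#' @param orientation `"genes_in_rows"` (default) or `"cells_in_rows"`,
#'   describing the file layout.
#' @param delimiter Field separator (default tab).
#' @param log1p Apply `log1p()` on read (default `FALSE`; inputs are assumed
#'   already log-scale).
#' @return An [expression_matrix()].
#' @export
read_dense_matrix <- function(path, orientation = c("genes_in_rows", "cells_in_rows"),
                              delimiter = "\t", log1p = FALSE) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop_scdrivers("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = delimiter,
                           check.names = FALSE, colClasses = "character",
                           comment.char = "", quote = "\"")
  row_names <- raw[[1L]]
  raw <- raw[-1L]
  rownames(raw) <- NULL
  chr <- as.matrix(raw)
  rownames(chr) <- row_names
  vals <- suppressWarnings(matrix(as.numeric(chr), nrow(chr), ncol(chr)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop_scdrivers(
      "could not parse '", chr[bad[1L], bad[2L]], "' as a number at data row ",
      bad[1L], " ('", row_names[bad[1L]], "'), column ", bad[2L],
      " ('", colnames(chr)[bad[2L]], "')")
  }
  if (orientation == "genes_in_rows") {
    expression_matrix(t(vals), gene_names = row_names,
                      cell_ids = colnames(chr), log1p = log1p)
  } else {
    expression_matrix(vals, gene_names = colnames(chr),
                      cell_ids = row_names, log1p = log1p)
  }
}

#' Write a dense delimited expression matrix
#'
#' Values are written with 17 significant digits so that a write/read
#' round-trip reproduces them to full double precision.
#'
#' @param x An [expression_matrix()].
#' @param path Output path.
#' @inheritParams read_dense_matrix
#' @return `path`, invisibly.
#' @export
write_dense_matrix <- function(x, path,
                               orientation = c("genes_in_rows", "cells_in_rows"),
                               delimiter = "\t") {
  orientation <- match.arg(orientation)
  validate_expression_matrix(x)
  m <- if (orientation == "genes_in_rows") t(unclass(x)) else unclass(x)
  chr <- matrix(formatC(m, digits = 17, format = "g"), nrow(m), ncol(m),
                dimnames = dimnames(m))
  out <- cbind(rownames(chr), chr)
  colnames(out)[1L] <- "name"
  utils::write.table(out, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a Matrix Market sparse expression matrix
#'
#' Reads a coordinate-format `.mtx` file plus two one-name-per-line sidecar
#' files (gene names and cell ids). Entries absent from the file are zeros.
#'
#' @param matrix_path Path to the MatrixMarket coordinate file.
#' @param genes_path Path to the gene-name sidecar.
#' @param cells_path Path to the cell-id sidecar.
#' @param orientation File layout, as in [read_dense_matrix()].
#' @param log1p Apply `log1p()` on read.
#' @return An [expression_matrix()].
#' @export
read_mtx <- function(matrix_path, genes_path, cells_path,
                     orientation = c("genes_in_rows", "cells_in_rows"),
                     log1p = FALSE) {
  orientation <- match.arg(orientation)
  sp <- Matrix::readMM(matrix_path)
  genes <- readLines(genes_path)
  cells <- readLines(cells_path)
  genes <- genes[nzchar(genes)]
  cells <- cells[nzchar(cells)]
  dims <- dim(sp)
  expected <- if (orientation == "genes_in_rows") {
    c(genes = dims[1L], cells = dims[2L])
  } else {
    c(cells = dims[1L], genes = dims[2L])
  }
  if (length(genes) != expected["genes"]) {
    stop_scdrivers("gene sidecar has ", length(genes),
                   " names but matrix header declares ", expected["genes"],
                   " genes")
  }
  if (length(cells) != expected["cells"]) {
    stop_scdrivers("cell sidecar has ", length(cells),
                   " ids but matrix header declares ", expected["cells"],
                   " cells")
  }
  dense <- as.matrix(sp)
  if (orientation == "genes_in_rows") dense <- t(dense)
  expression_matrix(dense, gene_names = genes, cell_ids = cells, log1p = log1p)
}

#' Write a Matrix Market sparse expression matrix
#'
#' Writes the nonzero entries in coordinate format (with 17 significant
#' digits, so round-trips are lossless) plus gene-name and cell-id sidecars.
#'
#' @inheritParams read_mtx
#' @param x An [expression_matrix()].
#' @return `matrix_path`, invisibly.
#' @export
write_mtx <- function(x, matrix_path, genes_path, cells_path,
                      orientation = c("genes_in_rows", "cells_in_rows")) {
  orientation <- match.arg(orientation)
  validate_expression_matrix(x)
  m <- if (orientation == "genes_in_rows") t(unclass(x)) else unclass(x)
  nz <- which(m != 0, arr.ind = TRUE)
  con <- file(matrix_path, "w")
  on.exit(close(con))
  writeLines(c("%%MatrixMarket matrix coordinate real general",
               sprintf("%d %d %d", nrow(m), ncol(m), nrow(nz))), con)
  if (nrow(nz) > 0L) {
    writeLines(sprintf("%d %d %s", nz[, 1L], nz[, 2L],
                       formatC(m[nz], digits = 17, format = "g")), con)
  }
  writeLines(colnames(x), genes_path)
  writeLines(rownames(x), cells_path)
  invisible(matrix_path)
}

#' Write a per-gene result table
#'
#' Writes a TSV with a header row, one record per gene, rows in the order
#' given (rankings stay rankings on disk).
#'
#' @param records A non-empty data.frame whose first column is the gene name.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(records, path) {
  records <- as.data.frame(records)
  if (nrow(records) == 0L) stop_scdrivers("gene table has no records")
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a per-gene result table written by [write_gene_table()]
#' @param path Path to the TSV.
#' @return A data.frame.
#' @export
read_gene_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "", quote = "\"")
}

#' Read a cell annotation table
#'
#' Expects a TSV with columns `cell_id` and `group`.
#' @param path Path to the TSV.
#' @return A [cell_annotation()].
#' @export
read_cell_annotation <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "")
  if (!all(c("cell_id", "group") %in% names(tab))) {
    stop_scdrivers("annotation file must have columns cell_id and group")
  }
  cell_annotation(tab$cell_id, tab$group)
}

#' Write a cell annotation table
#' @param annotation A [cell_annotation()] (or data.frame with `cell_id`,
#'   `group`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cell_annotation <- function(annotation, path) {
  utils::write.table(as.data.frame(annotation), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}
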