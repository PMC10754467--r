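# From per-subtype gene weights to ranked driver lists and networks.

#' Rank genes by weight
#'
#' Stable descending sort of the genes by their weight; ties keep the input
#' gene order.
#'
#' @param lam Numeric weight vector (no NaN/NA).
#' @param gene_names Character vector, same length as `lam`.
#' @return A data.frame with columns `gene`, `weight`, sorted by weight
#'   descending.
#' @export
rank_genes <- function(lam, gene_names) {
  if (length(lam) != length(gene_names)) {
    stop_scdrivers("lam and gene_names lengths differ")
  }
  if (anyNA(lam) || any(is.nan(lam))) {
    stop_scdrivers("gene weights contain NA/NaN")
  }
  ord <- order(-lam, method = "radix")  # radix sort is stable
  data.frame(gene = gene_names[ord], weight = lam[ord],
             stringsAsFactors = FALSE)
}

#' Driver-set size for a gene universe
#'
#' The number of genes in the top `fraction` of a ranking, using round half
#' up (minimum 1). Round half up is the only rounding rule consistent with
#' driver counts of 41, 52 and 59 out of gene universes of 820, 1048 and
#' 1170 at the default 5%.
#'
#' @param n Number of genes (>= 1).
#' @param fraction Fraction in (0, 1], default 0.05.
#' @return A positive integer.
#' @examples
#' top_fraction_count(820)  # 41
#' top_fraction_count(1048) # 52
#' top_fraction_count(1170) # 59
#' @export
top_fraction_count <- function(n, fraction = 0.05) {
  if (n < 1) stop_scdrivers("n must be >= 1")
  if (fraction <= 0 || fraction > 1) {
    stop_scdrivers("fraction must lie in (0, 1]")
  }
  max(1L, as.integer(floor(fraction * n + 0.5)))
}

#' Ranked driver genes of one subtype
#'
#' Sorts genes by weight (descending, stable) and takes the top `fraction`
#' (round half up) as the subtype's driver set.
#'
#' @inheritParams rank_genes
#' @param fraction Driver fraction, default 0.05 (top 5%).
#' @param subtype Optional subtype index recorded in the result.
#' @return An object of class `driver_ranking`: `subtype`, `ranked` (the
#'   gene/weight data.frame), `driver_set` (character vector), `fraction`.
#' @export
driver_ranking <- function(lam, gene_names, fraction = 0.05, subtype = NA) {
  ranked <- rank_genes(lam, gene_names)
  n_drivers <- top_fraction_count(length(gene_names), fraction)
  structure(list(subtype = subtype, ranked = ranked,
                 driver_set = ranked$gene[seq_len(n_drivers)],
                 fraction = fraction),
            class = "driver_ranking")
}

#' @export
print.driver_ranking <- function(x, ...) {
  cat(sprintf("driver_ranking (subtype %s): %d drivers of %d genes (top %g%%)\n",
              as.character(x$subtype), length(x$driver_set), nrow(x$ranked),
              100 * x$fraction))
  cat("  ", paste(utils::head(x$driver_set, 10), collapse = ", "),
      if (length(x$driver_set) > 10) "..." else "", "\n")
  invisible(x)
}

#' Driver rankings for every subtype of a fit
#'
#' @param fit A `csdgi_fit` (or an n x K gene-weight matrix with rownames).
#' @param fraction Driver fraction, default 0.05.
#' @return A list of [driver_ranking()] objects, one per subtype.
#' @export
driver_rankings <- function(fit, fraction = 0.05) {
  lam <- if (inherits(fit, "csdgi_fit")) fit$gene_weights else as.matrix(fit)
  genes <- rownames(lam)
  if (is.null(genes) && inherits(fit, "csdgi_fit")) genes <- fit$gene_names
  if (is.null(genes)) stop_scdrivers("gene weights carry no gene names")
  lapply(seq_len(ncol(lam)), function(k) {
    driver_ranking(lam[, k], genes, fraction, subtype = k)
  })
}

#' Driver genes shared between subtypes
#'
#' Exact intersection of the driver sets of two or more rankings, returned
#' in alphabetical order.
#'
#' @param rankings A list of [driver_ranking()] objects or character vectors.
#' @return A character vector (possibly empty).
#' @export
shared_drivers <- function(rankings) {
  if (length(rankings) < 2L) {
    stop_scdrivers("shared_drivers needs at least 2 driver sets")
  }
  sets <- lapply(rankings, function(r) {
    if (inherits(r, "driver_ranking")) r$driver_set else as.character(r)
  })
  sort(Reduce(intersect, sets))
}

#' Published breast-tumor subtype driver lists
#'
#' The two 41-gene driver lists reported for the two breast tumor-cell
#' subtypes, shipped as a plain-text fixture. Their intersection is the
#' 10-gene shared-driver set used as a worked example.
#'
#' @return A named list of two character vectors (`subtype1`, `subtype2`).
#' @export
breast_driver_lists <- function() {
  path <- system.file("extdata", "breast_subtype_drivers.tsv",
                      package = "scdrivers")
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  list(subtype1 = tab$gene[tab$subtype == 1],
       subtype2 = tab$gene[tab$subtype == 2])
}

#' Driver co-expression network
#'
#' For every unordered pair of the given genes, computes the Pearson
#' correlation across the cells of `x` and its two-sided p-value from the
#' t distribution with m - 2 degrees of freedom
#' (`t = r * sqrt((m - 2) / (1 - r^2))`). An edge is kept iff
#' `|r| >= r_min` and `p < alpha`. Constant genes have no defined
#' correlation and are dropped with a warning.
#'
#' @param x An [expression_matrix()] restricted to one subtype's cells
#'   (>= 3 cells).
#' @param genes Character vector of genes present in `x`.
#' @param r_min Minimum absolute correlation for an edge (default 0.3).
#' @param alpha Significance level for the edge p-value (default 0.05).
#' @return An object of class `coexpression_network`: `nodes` (genes used)
#'   and `edges` (data.frame `gene_a`, `gene_b`, `r`, `p_value`).
#' @export
coexpression_network <- function(x, genes, r_min = 0.3, alpha = 0.05) {
  m <- nrow(x)
  if (m < 3L) stop_scdrivers("co-expression needs >= 3 cells, got ", m)
  missing_genes <- setdiff(genes, colnames(x))
  if (length(missing_genes) > 0L) {
    stop_scdrivers("genes not in the matrix: ",
                   paste(utils::head(missing_genes, 5), collapse = ", "))
  }
  sub <- unclass(x)[, genes, drop = FALSE]
  sds <- apply(sub, 2L, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant gene(s) from the network: ",
            paste(genes[sds == 0], collapse = ", "), call. = FALSE)
    sub <- sub[, sds > 0, drop = FALSE]
  }
  nodes <- colnames(sub)
  ng <- length(nodes)
  edges <- data.frame(gene_a = character(0), gene_b = character(0),
                      r = numeric(0), p_value = numeric(0),
                      stringsAsFactors = FALSE)
  if (ng >= 2L) {
    C <- stats::cor(sub)
    pairs <- which(upper.tri(C), arr.ind = TRUE)
    r <- C[pairs]
    r_clip <- pmin(pmax(r, -1), 1)
    tstat <- ifelse(abs(r_clip) == 1, Inf,
                    r_clip * sqrt((m - 2) / (1 - r_clip^2)))
    p <- 2 * stats::pt(-abs(tstat), df = m - 2)
    keep <- abs(r) >= r_min & p < alpha
    edges <- data.frame(gene_a = nodes[pairs[keep, 1L]],
                        gene_b = nodes[pairs[keep, 2L]],
                        r = r[keep], p_value = p[keep],
                        stringsAsFactors = FALSE)
  }
  structure(list(nodes = nodes, edges = edges, r_min = r_min, alpha = alpha),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf("coexpression_network: %d nodes, %d edges (|r| >= %g, p < %g)\n",
              length(x$nodes), nrow(x$edges), x$r_min, x$alpha))
  invisible(x)
}

#' Write a network edge list as TSV
#' @param network A [coexpression_network()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
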