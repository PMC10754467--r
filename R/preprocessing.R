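# Gene filtering and EMD-based differential expression.

#' Preprocessing configuration
#'
#' @param prevalence_t Prevalence threshold t, in percent (default 6): genes
#'   expressed (value > 0) in fewer than t% or more than (100 - t)% of cells
#'   are removed.
#' @param variable_top_pct Keep the top r% most variable genes after mean
#'   detrending; 100 (default) disables the step.
#' @param emd_score_min Minimum EMD score for a gene to be selected as a DEG
#'   (default 0; real datasets use dataset-specific cut-offs such as 7 or 2).
#' @param alpha Significance level for the permutation p-value (default 0.05).
#' @param n_permutations Number of group-label permutations (default 100).
#' @param seed RNG seed driving the permutation order.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(prevalence_t = 6, variable_top_pct = 100,
                              emd_score_min = 0, alpha = 0.05,
                              n_permutations = 100, seed = 1) {
  if (prevalence_t <= 0 || prevalence_t >= 50) {
    stop_scdrivers("prevalence_t must lie in (0, 50), got ", prevalence_t)
  }
  if (variable_top_pct <= 0 || variable_top_pct > 100) {
    stop_scdrivers("variable_top_pct must lie in (0, 100]")
  }
  if (alpha <= 0 || alpha >= 1) stop_scdrivers("alpha must lie in (0, 1)")
  if (n_permutations < 1) stop_scdrivers("n_permutations must be >= 1")
  if (emd_score_min < 0) stop_scdrivers("emd_score_min must be >= 0")
  structure(list(prevalence_t = prevalence_t,
                 variable_top_pct = variable_top_pct,
                 emd_score_min = emd_score_min, alpha = alpha,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed)),
            class = "preprocess_config")
}

#' Filter genes by expression prevalence
#'
#' Removes genes expressed (value > 0) in fewer than t% of cells, and
#' likewise genes expressed in more than (100 - t)% of cells: near-absent
#' genes are noise, near-ubiquitous genes carry no subtype signal. Gene order
#' is preserved and the operation is idempotent.
#'
#' @param x An [expression_matrix()].
#' @param t Prevalence threshold in percent, in (0, 50). Default 6.
#' @return The filtered [expression_matrix()].
#' @export
filter_genes_by_prevalence <- function(x, t = 6) {
  if (t <= 0 || t >= 50) stop_scdrivers("t must lie in (0, 50), got ", t)
  prevalence <- colMeans(unclass(x) > 0)
  keep <- prevalence >= t / 100 & prevalence <= 1 - t / 100
  if (!any(keep)) {
    stop_scdrivers("prevalence filter at t = ", t,
                   "% removed every gene; use a smaller t")
  }
  x[, keep]
}

#' Select the most variable genes
#'
#' Ranks genes by a mean-detrended dispersion: genes are grouped into
#' `n_bins` equal-occupancy bins of mean expression, the dispersion
#' (variance / mean, mean floored at `eps`) is z-scored within each bin, and
#' the top `top_pct` percent by z-score are kept (original gene order
#' preserved). Detrending removes the systematic mean-variance relationship
#' of expression data so highly expressed genes do not dominate.
#'
#' @param x An [expression_matrix()] with at least 2 cells.
#' @param top_pct Percentage of genes to keep, in (0, 100]; 100 returns the
#'   input unchanged.
#' @param n_bins Number of mean-expression bins (default 20, reduced
#'   automatically when there are fewer genes than bins).
#' @param eps Floor for the mean in the dispersion denominator.
#' @return The filtered [expression_matrix()].
#' @export
select_variable_genes <- function(x, top_pct, n_bins = 20, eps = 1e-8) {
  if (top_pct <= 0 || top_pct > 100) {
    stop_scdrivers("top_pct must lie in (0, 100]")
  }
  if (top_pct == 100) return(x)
  if (nrow(x) < 2L) stop_scdrivers("variable-gene selection needs >= 2 cells")
  v <- unclass(x)
  mu <- colMeans(v)
  vars <- apply(v, 2L, stats::var)
  disp <- vars / pmax(mu, eps)
  n <- ncol(v)
  # each bin needs several genes for a meaningful within-bin z-score
  n_bins <- max(1L, min(as.integer(n_bins), n %/% 5L))
  # equal-occupancy bins over the mean-expression ranks
  bins <- ceiling(rank(mu, ties.method = "first") / (n / n_bins))
  z <- numeric(n)
  for (b in unique(bins)) {
    idx <- bins == b
    s <- stats::sd(disp[idx])
    z[idx] <- if (is.na(s) || s == 0) 0 else (disp[idx] - mean(disp[idx])) / s
  }
  n_keep <- ceiling(top_pct / 100 * n)
  keep_idx <- order(-z)[seq_len(n_keep)]
  x[, sort(keep_idx)]
}

#' Earth mover's distance between two samples
#'
#' The exact 1-D Wasserstein-1 distance between the empirical distributions
#' of `a` and `b`: the integral over the pooled value range of the absolute
#' difference of the two empirical CDFs. Symmetric, non-negative, zero iff
#' the empirical distributions coincide, and linear under common rescaling.
#'
#' @param a,b Non-empty numeric vectors.
#' @return A non-negative scalar.
#' @examples
#' emd_score(c(0, 0, 0), c(2, 2, 2)) # 2
#' @export
emd_score <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) {
    stop_scdrivers("emd_score requires two non-empty samples")
  }
  pooled <- c(a, b)
  ord <- order(pooled)
  vs <- pooled[ord]
  is_a <- c(rep(TRUE, length(a)), rep(FALSE, length(b)))[ord]
  emd_from_sorted(vs, is_a, length(a), length(b))
}

# EMD on a pre-sorted pooled sample: Fa, Fb are step CDFs evaluated at the
# sorted pooled values; tied runs contribute nothing because diff() is zero
# there, so within-run order is irrelevant.
emd_from_sorted <- function(vs, is_a, na, nb) {
  mtot <- length(vs)
  if (mtot < 2L) return(0)
  ca <- cumsum(is_a) / na
  cb <- cumsum(!is_a) / nb
  sum(abs(ca[-mtot] - cb[-mtot]) * diff(vs))
}

#' Binned-histogram variant of the EMD score
#'
#' Computes the Wasserstein-1 distance after binning both samples into a
#' shared histogram of width `binwidth`; provided for comparability with
#' histogram-based differential-expression tools. The exact [emd_score()] is
#' the default backend everywhere else in the package.
#'
#' @inheritParams emd_score
#' @param binwidth Positive bin width on the expression scale.
#' @return A non-negative scalar.
#' @export
emd_score_binned <- function(a, b, binwidth = 0.2) {
  if (length(a) == 0L || length(b) == 0L) {
    stop_scdrivers("emd_score_binned requires two non-empty samples")
  }
  if (binwidth <= 0) stop_scdrivers("binwidth must be positive")
  lo <- floor(min(a, b) / binwidth)
  hi <- ceiling(max(a, b) / binwidth)
  breaks <- seq(lo, hi + 1) * binwidth
  centers <- breaks[-length(breaks)] + binwidth / 2
  ha <- tabulate(findInterval(a, breaks, rightmost.closed = TRUE),
                 nbins = length(centers)) / length(a)
  hb <- tabulate(findInterval(b, breaks, rightmost.closed = TRUE),
                 nbins = length(centers)) / length(b)
  # W1 between the two histograms on the common grid
  sum(abs(cumsum(ha - hb))) * binwidth
}

#' Permutation test for differential expression by EMD
#'
#' For every gene, scores the separation between the two cell groups (e.g.
#' tumor vs non-tumor) with the earth mover's distance, and attaches a
#' permutation p-value: group labels are randomly reassigned (group sizes
#' fixed) `n_permutations` times and the add-one estimator
#' p = (1 + #\{permuted score >= observed\}) / (1 + n_permutations) is used,
#' so the smallest attainable p is 1/(n_permutations + 1). Benjamini-Hochberg
#' q-values are attached; selection follows the raw p-value and the score
#' cut-off.
#'
#' @param x An [expression_matrix()].
#' @param groups A [cell_annotation()] or a vector with exactly two distinct
#'   labels, each present in at least 2 cells.
#' @param config A [preprocess_config()]; `alpha`, `emd_score_min`,
#'   `n_permutations` and `seed` are used.
#' @return A data.frame with columns `gene`, `emd_score`, `p_value`,
#'   `q_value`, `selected`, in input gene order.
#' @export
deg_test <- function(x, groups, config = preprocess_config()) {
  g <- align_annotation(x, groups)
  g <- as.character(g)
  lev <- sort(unique(g))
  if (length(lev) != 2L) {
    stop_scdrivers("deg_test needs exactly two groups, got ",
                   length(lev), " (", paste(lev, collapse = ", "), ")")
  }
  is_a <- g == lev[1L]
  na <- sum(is_a); nb <- sum(!is_a)
  if (na < 2L || nb < 2L) {
    stop_scdrivers("each group needs >= 2 cells (", lev[1L], ": ", na,
                   ", ", lev[2L], ": ", nb, ")")
  }
  v <- unclass(x)
  m <- nrow(v); n <- ncol(v)
  nperm <- config$n_permutations

  # per-gene sort order is fixed across permutations; only labels move
  ords <- lapply(seq_len(n), function(j) order(v[, j]))
  sorted_vals <- lapply(seq_len(n), function(j) v[ords[[j]], j])
  gaps <- lapply(sorted_vals, diff)

  observed <- vapply(seq_len(n), function(j) {
    sa <- is_a[ords[[j]]]
    emd_from_sorted(sorted_vals[[j]], sa, na, nb)
  }, numeric(1))

  exceed <- integer(n)
  local_seed(config$seed, {
    for (p in seq_len(nperm)) {
      perm <- sample(is_a)
      for (j in seq_len(n)) {
        sa <- perm[ords[[j]]]
        ca <- cumsum(sa) / na
        cb <- cumsum(!sa) / nb
        s <- sum(abs(ca[-m] - cb[-m]) * gaps[[j]])
        if (s >= observed[j] - 1e-12) exceed[j] <- exceed[j] + 1L
      }
    }
  })

  p_value <- (1 + exceed) / (1 + nperm)
  q_value <- stats::p.adjust(p_value, method = "BH")
  selected <- observed >= config$emd_score_min & p_value < config$alpha
  data.frame(gene = colnames(x), emd_score = observed, p_value = p_value,
             q_value = q_value, selected = selected,
             stringsAsFactors = FALSE)
}
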