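# Classification/clustering metrics, subtype-number estimation, and the
# gene-set benchmarking harness.

#' Classification metrics from confusion counts
#'
#' Accuracy, precision, recall and F1 from true/false positive/negative
#' counts. A metric whose denominator is zero is reported as `NA`
#' (undefined), except F1 when precision + recall = 0, which is reported as
#' 0 by convention (flagged via the `f1_zero_convention` attribute).
#'
#' @param tp,tn,fp,fn Non-negative integer counts, not all zero.
#' @return A named list: `accuracy`, `precision`, `recall`, `f1`.
#' @examples
#' classification_metrics(tp = 8, tn = 6, fp = 2, fn = 4)
#' @export
classification_metrics <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0)) stop_scdrivers("confusion counts must be >= 0")
  if (sum(counts) == 0) stop_scdrivers("all confusion counts are zero")
  accuracy <- (tp + tn) / sum(counts)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  flagged <- FALSE
  if (is.na(precision) || is.na(recall)) {
    f1 <- NA_real_
  } else if (precision + recall == 0) {
    f1 <- 0
    flagged <- TRUE
  } else {
    f1 <- 2 * precision * recall / (precision + recall)
  }
  out <- list(accuracy = accuracy, precision = precision, recall = recall,
              f1 = f1)
  attr(out, "f1_zero_convention") <- flagged
  out
}

# Confusion counts of a binary prediction against truth.
confusion_counts <- function(truth, predicted, positive) {
  tp <- sum(truth == positive & predicted == positive)
  tn <- sum(truth != positive & predicted != positive)
  fp <- sum(truth != positive & predicted == positive)
  fn <- sum(truth == positive & predicted != positive)
  list(tp = tp, tn = tn, fp = fp, fn = fn)
}

#' Adjusted Rand index
#'
#' Chance-corrected pair-counting agreement between two partitions,
#' `ARI = (RI - E[RI]) / (max(RI) - E[RI])` under the permutation model.
#' Symmetric, invariant under relabeling, 1 iff the partitions coincide.
#'
#' @param labels_a,labels_b Label vectors of equal length (>= 2).
#' @return A scalar, at most 1.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop_scdrivers("label vectors have different lengths (",
                   length(labels_a), " vs ", length(labels_b), ")")
  }
  if (length(labels_a) < 2L) stop_scdrivers("need at least 2 observations")
  tab <- table(labels_a, labels_b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  ntot <- choose(length(labels_a), 2)
  expected <- ai * bj / ntot
  maximum <- (ai + bj) / 2
  if (maximum == expected) {
    return(as.numeric(nij == maximum))  # both partitions trivial
  }
  (nij - expected) / (maximum - expected)
}

#' Within-cluster sum-of-squares curve and elbow
#'
#' Runs k-means for k = 1..k_max, keeping the best (lowest) total
#' within-cluster sum of squares over `restarts` starts per k, and picks the
#' elbow: the interior k maximizing the second difference
#' `wss[k-1] - 2 wss[k] + wss[k+1]`. The curve is returned so the choice can
#' be inspected and overridden.
#'
#' @param x An [expression_matrix()] or numeric matrix (rows clustered).
#' @param k_max Largest k to try (must be < number of rows; elbow needs
#'   k_max >= 3).
#' @param restarts k-means restarts per k (default 10).
#' @param seed RNG seed.
#' @param iter_max k-means iteration cap per run.
#' @return An object of class `wss_curve`: `k_values`, `wss`, `chosen_k`.
#' @export
wss_curve <- function(x, k_max, restarts = 10, seed = 1, iter_max = 50) {
  X <- as.matrix(unclass(x))
  if (k_max >= nrow(X)) {
    stop_scdrivers("k_max (", k_max, ") must be smaller than the number of",
                   " rows (", nrow(X), ")")
  }
  if (k_max < 1) stop_scdrivers("k_max must be >= 1")
  wss <- numeric(k_max)
  local_seed(seed, {
    for (k in seq_len(k_max)) {
      km <- stats::kmeans(X, centers = k, nstart = restarts,
                          iter.max = iter_max)
      wss[k] <- km$tot.withinss
    }
  })
  chosen <- choose_k_elbow(wss)
  structure(list(k_values = seq_len(k_max), wss = wss, chosen_k = chosen),
            class = "wss_curve")
}

#' Elbow rule on a WSS curve
#'
#' Returns the interior k with the largest second difference of the WSS
#' curve (the sharpest bend); `NA` when the curve has fewer than 3 points.
#'
#' @param wss Numeric vector of WSS values for k = 1..length(wss).
#' @return The chosen k, or `NA`.
#' @export
choose_k_elbow <- function(wss) {
  if (length(wss) < 3L) return(NA_integer_)
  interior <- 2:(length(wss) - 1L)
  curv <- wss[interior - 1L] - 2 * wss[interior] + wss[interior + 1L]
  interior[which.max(curv)]
}

#' @export
print.wss_curve <- function(x, ...) {
  cat("wss_curve (k, WSS):\n")
  for (i in seq_along(x$k_values)) {
    cat(sprintf("  %2d  %.4g%s\n", x$k_values[i], x$wss[i],
                if (!is.na(x$chosen_k) && x$k_values[i] == x$chosen_k)
                  "  <- elbow" else ""))
  }
  invisible(x)
}

#' Benchmark ranked gene sets by classification and clustering
#'
#' Evaluation fixture comparing gene-selection methods: for each method and
#' each gene-set size, the matrix is restricted to the top-`size` genes of
#' that method's ranking and scored by (a) cross-validated classification
#' accuracy and F1 with an SVM and a random forest, and (b) clustering ARI
#' against the true groups with k-means and a Gaussian mixture model.
#' Results are averaged over `n_repeats` fold/restart shuffles.
#'
#' @param x An [expression_matrix()].
#' @param true_groups A [cell_annotation()] or label vector (two or more
#'   groups; classification requires exactly two).
#' @param gene_sets Named list: method name -> ranked character vector of
#'   genes (best first).
#' @param sizes Integer vector of gene-set sizes (default `seq(2, 20, 2)`).
#' @param n_repeats Number of repeats averaged (default 10).
#' @param n_folds Cross-validation folds (default 5).
#' @param seed RNG seed.
#' @return A data.frame: `method`, `n_genes`, `task`, `model`, `metric`,
#'   `value`.
#' @export
benchmark_gene_set <- function(x, true_groups, gene_sets,
                               sizes = seq(2, 20, 2), n_repeats = 10,
                               n_folds = 5, seed = 1) {
  for (pkg in c("e1071", "randomForest", "mclust")) {
    if (!requireNamespace(pkg, quietly = TRUE)) {
      stop_scdrivers("benchmark_gene_set needs the '", pkg, "' package")
    }
  }
  g <- as.factor(align_annotation(x, true_groups))
  classify <- nlevels(g) == 2L
  positive <- levels(g)[1L]
  for (nm in names(gene_sets)) {
    missing_genes <- setdiff(gene_sets[[nm]], colnames(x))
    if (length(missing_genes) > 0L) {
      stop_scdrivers("method '", nm, "' names unknown gene(s): ",
                     paste(utils::head(missing_genes, 5), collapse = ", "))
    }
    if (max(sizes) > length(gene_sets[[nm]])) {
      stop_scdrivers("size ", max(sizes), " exceeds the ranked list of '",
                     nm, "' (", length(gene_sets[[nm]]), " genes)")
    }
  }
  rows <- list()
  for (nm in names(gene_sets)) {
    for (size in sizes) {
      sub <- unclass(x)[, gene_sets[[nm]][seq_len(size)], drop = FALSE]
      acc <- f1 <- ari_km <- ari_gmm <- matrix(NA_real_, n_repeats, 2)
      for (r in seq_len(n_repeats)) {
        rep_seed <- derive_seed(seed, r)
        if (classify) {
          cv <- cv_classify(sub, g, positive, n_folds, rep_seed)
          acc[r, ] <- cv$accuracy
          f1[r, ] <- cv$f1
        }
        local_seed(rep_seed, {
          km <- stats::kmeans(sub, centers = nlevels(g), nstart = 5,
                              iter.max = 50)
          ari_km[r, 1] <- adjusted_rand_index(g, km$cluster)
          # Mclust resolves mclustBIC in the caller's frame, so alias it
          mclustBIC <- mclust::mclustBIC
          gmm <- tryCatch(
            mclust::Mclust(sub, G = nlevels(g), verbose = FALSE),
            error = function(e) NULL)
          ari_gmm[r, 1] <- if (is.null(gmm)) NA_real_ else
            adjusted_rand_index(g, gmm$classification)
        })
      }
      add <- function(task, mdl, metric, vals) {
        rows[[length(rows) + 1L]] <<- data.frame(
          method = nm, n_genes = size, task = task, model = mdl,
          metric = metric, value = mean(vals, na.rm = TRUE),
          stringsAsFactors = FALSE)
      }
      if (classify) {
        add("classification", "svm", "accuracy", acc[, 1])
        add("classification", "rf", "accuracy", acc[, 2])
        add("classification", "svm", "f1", f1[, 1])
        add("classification", "rf", "f1", f1[, 2])
      }
      add("clustering", "kmeans", "ari", ari_km[, 1])
      add("clustering", "gmm", "ari", ari_gmm[, 1])
    }
  }
  do.call(rbind, rows)
}

# Stratified k-fold CV with SVM and random forest; returns mean accuracy and
# F1 per model (columns: svm, rf).
cv_classify <- function(sub, g, positive, n_folds, seed) {
  m <- nrow(sub)
  folds <- integer(m)
  local_seed(seed, {
    for (lev in levels(g)) {
      idx <- which(g == lev)
      folds[idx] <- sample(rep(seq_len(n_folds), length.out = length(idx)))
    }
  })
  acc <- f1 <- matrix(NA_real_, n_folds, 2)
  for (f in seq_len(n_folds)) {
    test <- folds == f
    if (all(test) || !any(test)) next
    if (nlevels(droplevels(g[!test])) < 2L) next
    tr_x <- sub[!test, , drop = FALSE]
    tr_y <- g[!test]
    te_x <- sub[test, , drop = FALSE]
    te_y <- g[test]
    pred_svm <- tryCatch({
      fit <- e1071::svm(tr_x, tr_y)
      stats::predict(fit, te_x)
    }, error = function(e) NULL)
    pred_rf <- tryCatch({
      fit <- randomForest::randomForest(tr_x, tr_y)
      stats::predict(fit, te_x)
    }, error = function(e) NULL)
    score <- function(pred) {
      if (is.null(pred)) return(c(NA_real_, NA_real_))
      cc <- confusion_counts(te_y, pred, positive)
      mm <- classification_metrics(cc$tp, cc$tn, cc$fp, cc$fn)
      c(mm$accuracy, if (is.na(mm$f1)) 0 else mm$f1)
    }
    s1 <- score(pred_svm); s2 <- score(pred_rf)
    acc[f, ] <- c(s1[1], s2[1])
    f1[f, ] <- c(s1[2], s2[2])
  }
  list(accuracy = colMeans(acc, na.rm = TRUE),
       f1 = colMeans(f1, na.rm = TRUE))
}

#' Driver-recovery score against planted truth
#'
#' Scores how well the inferred driver sets recover the planted driver
#' genes: the union of all inferred driver sets is intersected with the
#' union of all planted sets and the overlap is divided by
#' `min(|inferred union|, |planted union|)` — recall capped by the inferred
#' sets' capacity, identical to plain recall whenever at least as many
#' genes are inferred as were planted. Using the unions makes the score
#' invariant under permutation of the (arbitrary) subtype indices on either
#' side.
#'
#' @param rankings A list of [driver_ranking()] objects (one per inferred
#'   subtype) or a list of character vectors.
#' @param truth_driver_sets List of planted driver gene sets, indexed by
#'   planted subtype.
#' @return A scalar in [0, 1].
#' @export
driver_recovery <- function(rankings, truth_driver_sets) {
  inferred <- unique(unlist(lapply(rankings, function(r) {
    if (inherits(r, "driver_ranking")) r$driver_set else as.character(r)
  })))
  planted <- unique(unlist(truth_driver_sets))
  if (length(inferred) == 0L || length(planted) == 0L) {
    stop_scdrivers("driver_recovery needs non-empty gene sets")
  }
  length(intersect(inferred, planted)) /
    min(length(inferred), length(planted))
}
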