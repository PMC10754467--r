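test_that("classification metrics follow the confusion-count formulas", {
  perfect <- classification_metrics(10, 10, 0, 0)
  expect_equal(unlist(perfect), c(accuracy = 1, precision = 1, recall = 1,
                                  f1 = 1))
  m <- classification_metrics(8, 6, 2, 4)
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$precision, 0.8)
  expect_equal(m$recall, 2 / 3)
  expect_equal(m$f1, 2 * 0.8 * (2 / 3) / (0.8 + 2 / 3))
  expect_equal(m$f1, 8 / 11)

  # zero precision and recall -> f1 reported as 0, flagged
  z <- classification_metrics(0, 5, 3, 2)
  expect_equal(z$precision, 0)
  expect_equal(z$recall, 0)
  expect_equal(z$f1, 0)
  expect_true(attr(z, "f1_zero_convention"))

  # undefined denominators are NA
  nd <- classification_metrics(0, 5, 0, 0)
  expect_true(is.na(nd$precision))
  expect_error(classification_metrics(0, 0, 0, 0), "zero")
})

test_that("adjusted Rand index agrees with the pair-counting oracle", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c("b", "b", "a", "a")), 1)
  a4 <- c(1, 1, 2, 2)
  b4 <- c(1, 2, 1, 2)
  expect_equal(adjusted_rand_index(a4, b4), oracle_ari(a4, b4))

  set.seed(18)
  for (rep in 1:15) {
    m <- sample(5:50, 1)
    la <- sample(1:4, m, replace = TRUE)
    lb <- sample(1:3, m, replace = TRUE)
    ari <- adjusted_rand_index(la, lb)
    expect_equal(ari, oracle_ari(la, lb), tolerance = 1e-12)
    expect_equal(ari, adjusted_rand_index(lb, la))
    expect_lte(ari, 1)
    # relabeling invariance
    expect_equal(adjusted_rand_index(la, lb),
                 adjusted_rand_index(5 - la, lb))
  }
  expect_error(adjusted_rand_index(1:3, 1:4), "lengths")
})

test_that("ARI agrees with mclust and is near zero for random partitions", {
  skip_if_not_installed("mclust")
  set.seed(19)
  vals <- numeric(200)
  for (rep in 1:200) {
    la <- sample(1:3, 30, replace = TRUE)
    lb <- sample(1:3, 30, replace = TRUE)
    vals[rep] <- adjusted_rand_index(la, lb)
    if (rep <= 20) {
      expect_equal(vals[rep], mclust::adjustedRandIndex(la, lb),
                   tolerance = 1e-12)
    }
  }
  expect_lt(abs(mean(vals)), 0.05)
})

test_that("wss curves are monotone with closed-form k = 1 and elbow at 2 blobs", {
  X <- make_blobs(seed = 3)
  curve <- wss_curve(X, k_max = 6, restarts = 10, seed = 1)
  expect_equal(curve$wss[1], sum(scale(X, scale = FALSE)^2))
  expect_true(all(diff(curve$wss) <= 1e-8))
  expect_identical(curve$chosen_k, 2L)
  expect_error(wss_curve(X, k_max = 100), "smaller")
  expect_true(is.na(choose_k_elbow(c(10, 5))))
})

test_that("benchmark harness separates informative from noise gene sets", {
  skip_if_not_installed("e1071")
  skip_if_not_installed("randomForest")
  skip_if_not_installed("mclust")
  sim <- simulate_two_group(
    synthetic_scenario(m_cells = 80, n_genes = 40, dropout_rate = 0.2,
                       seed = 21),
    n_deg = 10, deg_shift = 2.5)
  planted <- sim$truth$deg_genes
  noise <- setdiff(gene_names(sim$matrix), planted)
  sets <- list(planted = planted, noise = noise[1:10])
  res <- benchmark_gene_set(sim$matrix, sim$annotation, sets,
                            sizes = c(4, 8), n_repeats = 2, n_folds = 3,
                            seed = 5)
  expect_true(all(c("method", "n_genes", "task", "model", "metric",
                    "value") %in% names(res)))
  acc <- function(meth, size) {
    mean(res$value[res$method == meth & res$n_genes == size &
                     res$metric == "accuracy"])
  }
  ari <- function(meth, size) {
    mean(res$value[res$method == meth & res$n_genes == size &
                     res$metric == "ari"])
  }
  # informative genes classify well; noise genes hover near majority rate
  expect_gt(acc("planted", 8), 0.85)
  expect_lt(acc("noise", 8), 0.65)
  expect_gt(ari("planted", 8), ari("noise", 8))

  expect_error(
    benchmark_gene_set(sim$matrix, sim$annotation,
                       list(bad = c(planted[1:4], "nope")), sizes = 2),
    "unknown gene")
  expect_error(
    benchmark_gene_set(sim$matrix, sim$annotation,
                       list(short = planted[1:3]), sizes = 8),
    "exceeds")
})

test_that("driver recovery scores unions with capacity capping", {
  truth <- list(s1 = c("a", "b", "c"), s2 = c("d", "e", "f"))
  expect_equal(driver_recovery(list(c("a", "d")), truth), 1)
  expect_equal(driver_recovery(list(c("a", "x")), truth), 0.5)
  expect_equal(driver_recovery(list(c("x", "y")), truth), 0)
  # invariant to branch order
  r1 <- driver_recovery(list(c("a", "b"), c("d", "x")), truth)
  r2 <- driver_recovery(list(c("d", "x"), c("a", "b")), truth)
  expect_equal(r1, r2)
})
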