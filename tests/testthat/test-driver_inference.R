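test_that("rank_genes sorts stably by descending weight", {
  expect_identical(rank_genes(c(0.1, 0.9, 0.5), c("g1", "g2", "g3"))$gene,
                   c("g2", "g3", "g1"))
  # uniform weights keep input order (stability)
  expect_identical(rank_genes(rep(0.3, 4), paste0("g", 1:4))$gene,
                   paste0("g", 1:4))
  expect_error(rank_genes(c(0.2, NaN), c("a", "b")), "NA/NaN")

  set.seed(14)
  w <- runif(1000)
  nm <- paste0("g", seq_along(w))
  ranked <- rank_genes(w, nm)
  ord <- sort.list(w, decreasing = TRUE, method = "shell")  # oracle sort
  expect_identical(ranked$gene, nm[ord])
  expect_true(all(diff(ranked$weight) <= 0))
})

test_that("top-fraction counts use round half up", {
  expect_identical(top_fraction_count(820, 0.05), 41L)
  expect_identical(top_fraction_count(1048, 0.05), 52L)
  expect_identical(top_fraction_count(1170, 0.05), 59L)
  expect_identical(top_fraction_count(20, 0.05), 1L)
  expect_identical(top_fraction_count(3, 0.01), 1L)  # minimum 1
  expect_error(top_fraction_count(10, 0), "fraction")
})

test_that("driver rankings and shared sets behave like set operations", {
  lam <- c(a = 0.9, b = 0.1, c = 0.5, d = 0.8)
  r <- driver_ranking(lam, names(lam), fraction = 0.5)
  expect_identical(r$driver_set, c("a", "d"))
  expect_identical(shared_drivers(list(c("x", "y"), c("z"))), character(0))
  expect_identical(shared_drivers(list(c("y", "x"), c("x", "y"))),
                   c("x", "y"))
  expect_error(shared_drivers(list(c("x"))), "at least 2")

  # driver sets are subsets of the universe, size invariant to input order
  set.seed(15)
  w <- runif(40)
  nm <- paste0("g", 1:40)
  perm <- sample(40)
  r1 <- driver_ranking(w, nm)
  r2 <- driver_ranking(w[perm], nm[perm])
  expect_setequal(r1$driver_set, r2$driver_set)
  expect_true(all(r1$driver_set %in% nm))
})

test_that("published breast driver lists intersect in the 10 shared genes", {
  lists <- breast_driver_lists()
  expect_length(lists$subtype1, 41)
  expect_length(lists$subtype2, 41)
  shared <- shared_drivers(lists)
  expect_identical(shared,
                   sort(c("MGP", "SCGB2A2", "HLA-DRA", "TFF3", "AGR2",
                          "TM4SF1", "MGST1", "HLA-B", "CLU", "AZGP1")))
})

test_that("co-expression networks match the closed-form t-test oracle", {
  set.seed(16)
  m <- 10
  base <- rnorm(m)
  vals <- cbind(base, -base + 10, rnorm(m), rnorm(m)) + 20
  x <- expression_matrix(vals - min(vals),
                         gene_names = c("g1", "g1neg", "g3", "g4"))
  net <- coexpression_network(x, gene_names(x), r_min = 0.99, alpha = 0.05)
  pair <- net$edges[net$edges$gene_a == "g1" & net$edges$gene_b == "g1neg", ]
  expect_equal(pair$r, -1)
  expect_equal(pair$p_value, 0)

  # copy of a gene under another name -> r = 1
  x2 <- expression_matrix(cbind(vals[, 1], vals[, 1], vals[, 3]) + 25,
                          gene_names = c("a", "a_copy", "c"))
  net2 <- coexpression_network(x2, gene_names(x2), r_min = 0.99)
  expect_equal(net2$edges$r[net2$edges$gene_a == "a" &
                              net2$edges$gene_b == "a_copy"], 1)

  # oracle: r from cor(), p from the t distribution with m - 2 df
  set.seed(17)
  v3 <- matrix(abs(rnorm(10 * 3)), 10, 3)
  colnames(v3) <- c("u", "v", "w")
  x3 <- expression_matrix(v3, gene_names = c("u", "v", "w"))
  net3 <- coexpression_network(x3, c("u", "v", "w"), r_min = 0, alpha = 1)
  for (i in seq_len(nrow(net3$edges))) {
    e <- net3$edges[i, ]
    ct <- cor.test(v3[, e$gene_a], v3[, e$gene_b])
    expect_equal(e$r, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(e$p_value, ct$p.value, tolerance = 1e-12)
  }

  # no self edges, each unordered pair at most once
  keys <- paste(pmin(net3$edges$gene_a, net3$edges$gene_b),
                pmax(net3$edges$gene_a, net3$edges$gene_b))
  expect_false(any(net3$edges$gene_a == net3$edges$gene_b))
  expect_false(any(duplicated(keys)))

  # constant genes are dropped with a warning
  v4 <- cbind(v3, 2)
  x4 <- expression_matrix(v4, gene_names = c("u", "v", "w", "flat"))
  expect_warning(net4 <- coexpression_network(x4, gene_names(x4)), "flat")
  expect_false("flat" %in% net4$nodes)
  expect_error(coexpression_network(x3[1:2, ], c("u", "v")), ">= 3 cells")
  expect_error(coexpression_network(x3, c("u", "nope")), "nope")
})

test_that("planted driver modules appear in the subtype co-expression network", {
  # strong program variability and light dropout make the module edges
  # individually detectable at this sample size
  sim <- simulate_subtypes(synthetic_scenario(m_cells = 300,
                                              dropout_rate = 0.1,
                                              program_sd = 0.8, seed = 11))
  lab <- sim$truth$labels
  own <- sim$truth$driver_sets[[1]]
  net <- coexpression_network(sim$matrix[lab == 1, ], gene_names(sim$matrix),
                              r_min = 0.2, alpha = 0.01)
  in_module <- net$edges$gene_a %in% own & net$edges$gene_b %in% own
  n_pairs_module <- choose(length(own), 2)
  n_pairs_total <- choose(length(net$nodes), 2)
  # module edge density far above background density
  expect_gt(sum(in_module) / n_pairs_module,
            5 * sum(!in_module) / (n_pairs_total - n_pairs_module))
})
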