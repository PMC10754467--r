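test_that("initialization is seed-deterministic and branch-distinct", {
  cfg <- model_config(n_subtypes = 2, seed = 5)
  m1 <- init_model(cfg, 20)
  m2 <- init_model(cfg, 20)
  expect_identical(m1, m2)
  m3 <- init_model(model_config(n_subtypes = 2, seed = 6), 20)
  expect_false(identical(m1$branches[[1]]$V, m3$branches[[1]]$V))
  expect_false(identical(m1$branches[[1]]$V, m1$branches[[2]]$V))
  expect_equal(m1$branches[[1]]$M, rep(1, 20))
  expect_equal(m1$branches[[1]]$E, rep(0, 20))

  # initial loss is finite on random data
  set.seed(1)
  X <- matrix(abs(rnorm(50 * 30)), 50, 30)
  cfg30 <- model_config(n_subtypes = 2, seed = 0)
  tl <- total_loss(X, init_model(cfg30, 30))
  expect_true(is.finite(tl$loss))
})

test_that("encoder residual blocks follow x + ReLU(Wx + b)", {
  # zero weights -> identity (pure skip connections)
  enc0 <- list(W = list(matrix(0, 3, 3), matrix(0, 3, 3)),
               b = list(numeric(3), numeric(3)))
  x <- c(1.5, 0, 2)
  expect_equal(encoder_forward(x, enc0), x)

  # hand example: p = 1, W = [[1,0],[0,-1]], x = (1,1) -> (2,1)
  enc1 <- list(W = list(matrix(c(1, 0, 0, -1), 2, 2, byrow = TRUE)),
               b = list(numeric(2)))
  expect_equal(encoder_forward(c(1, 1), enc1), c(2, 1))

  # sequential blocks equal the telescoped residual sum
  set.seed(2)
  enc <- list(W = lapply(1:3, function(i) matrix(rnorm(16, sd = 0.3), 4, 4)),
              b = lapply(1:3, function(i) rnorm(4, sd = 0.1)))
  x <- rnorm(4)
  out <- encoder_forward(x, enc)
  acc <- x
  manual <- x
  for (l in 1:3) {
    h <- pmax(enc$W[[l]] %*% manual + enc$b[[l]], 0)
    manual <- manual + h
  }
  expect_equal(out, drop(manual))
})

test_that("low-rank propagation uses the zero-diagonal similarity", {
  # one-hot V: only diagonal mass, which is removed -> D = 0
  br <- list(V = matrix(c(0, 1, 0), 3, 1))
  expect_equal(lowrank_propagate(c(1, 2, 3), br), rep(0, 3))
  expect_equal(lowrank_propagate(rep(0, 3), list(V = matrix(rnorm(3), 3, 1))),
               rep(0, 3))
  # hand example: V = (1,1,0), xp = (1,2,3) -> (tanh 2, tanh 1, 0)
  br2 <- list(V = matrix(c(1, 1, 0), 3, 1))
  expect_equal(lowrank_propagate(c(1, 2, 3), br2), c(tanh(2), tanh(1), 0))
  # matrix and vector paths agree
  xp <- matrix(rnorm(6), 2, 3)
  D <- lowrank_propagate(xp, br2)
  expect_equal(D[1, ], lowrank_propagate(xp[1, ], br2))
  expect_true(all(abs(D) < 1))
})

test_that("decoder applies shared tanh layer and branch affine read-out", {
  dec0 <- list(G = matrix(0, 2, 2), e = numeric(2))
  br <- list(M = c(2, 2), E = c(1, 1))
  expect_equal(decoder_forward(c(0.3, -0.2), dec0, br), c(1, 1))
  br0 <- list(M = c(0, 0), E = c(5, -5))
  dec <- list(G = diag(2), e = numeric(2))
  expect_equal(decoder_forward(c(0.5, -0.5), dec, br0), c(5, -5))
  expect_equal(decoder_forward(c(0.5, -0.5), dec, br),
               c(1 + 2 * tanh(0.5), 1 - 2 * tanh(0.5)))
})

test_that("reconstructions are bounded by |M| + |E|", {
  set.seed(4)
  n <- 6
  dec <- list(G = matrix(rnorm(n * n), n, n), e = rnorm(n))
  br <- list(M = rnorm(n), E = rnorm(n))
  D <- matrix(rnorm(5 * n, sd = 2), 5, n)
  xhat <- decoder_forward(D, dec, br)
  bound <- matrix(abs(br$M) + abs(br$E), 5, n, byrow = TRUE)
  expect_true(all(abs(xhat) <= bound + 1e-12))
})

test_that("compute_lambda matches the dense eigendecomposition oracle", {
  # worked example: V = (1,2,2) -> every row of L is (0.2,0.4,0.4),
  # lambda = (1,2,2)/3
  lam <- compute_lambda(matrix(c(1, 2, 2), 3, 1))
  expect_equal(lam$lambda, c(1, 2, 2) / 3)
  expect_equal(compute_lambda(matrix(c(1, 2, 2), 3, 1),
                              method = "eigen")$lambda, c(1, 2, 2) / 3)

  # constant V -> uniform weights 1/sqrt(n)
  expect_equal(compute_lambda(matrix(1, 4, 1))$lambda, rep(0.5, 4))

  set.seed(8)
  for (rep in 1:25) {
    n <- sample(3:20, 1)
    V <- matrix(rnorm(n), n, 1)
    lam_cf <- compute_lambda(V)$lambda
    expect_equal(lam_cf, abs(V[, 1]) / sqrt(sum(V^2)), tolerance = 1e-12)
    expect_equal(lam_cf, oracle_lambda(V), tolerance = 1e-8)
    expect_equal(lam_cf, compute_lambda(V, method = "eigen")$lambda,
                 tolerance = 1e-8)
    # sign invariance and unit norm
    expect_equal(compute_lambda(-V)$lambda, lam_cf)
    expect_equal(sum(lam_cf^2), 1)
    expect_true(all(lam_cf >= 0))
  }

  # rank-2 factors still agree with the oracle
  for (rep in 1:10) {
    V2 <- matrix(rnorm(12), 6, 2)
    expect_equal(compute_lambda(V2)$lambda, oracle_lambda(V2),
                 tolerance = 1e-8)
  }
})

test_that("weighted loss and total loss follow the min-over-branches rule", {
  expect_equal(weighted_cell_loss(c(1, 2), c(1, 2), c(0.5, 0.5)), 0)
  expect_equal(weighted_cell_loss(c(1, 0), c(0, 0), c(1, 1) / sqrt(2)), 0.5)
  expect_equal(weighted_cell_loss(c(1, 2), c(0, 0), c(0, 0)), 0)

  set.seed(10)
  n <- 8; m <- 12
  X <- matrix(abs(rnorm(m * n)), m, n)
  cfg <- model_config(n_subtypes = 3, seed = 3)
  model <- init_model(cfg, n)
  lam <- scdrivers:::model_lambda(model)
  tl <- total_loss(X, model)

  # brute-force enumeration per cell over branches
  manual <- sapply(seq_len(m), function(i) {
    min(sapply(seq_len(3), function(k) {
      xp <- encoder_forward(X[i, ], model$encoder)
      D <- lowrank_propagate(xp, model$branches[[k]])
      xhat <- decoder_forward(D, model$decoder, model$branches[[k]])
      weighted_cell_loss(X[i, ], xhat, lam[, k])
    }))
  })
  expect_equal(tl$loss, mean(manual))
  expect_equal(tl$assignment$losses[cbind(seq_len(m), tl$assignment$labels)],
               apply(tl$assignment$losses, 1, min))

  # min over k is never above any single branch's loss
  expect_true(all(tl$assignment$losses >=
                    apply(tl$assignment$losses, 1, min) - 1e-12))

  # single branch: all labels 1, loss = mean branch loss
  cfg1 <- model_config(n_subtypes = 1, seed = 3)
  tl1 <- total_loss(X, init_model(cfg1, n))
  expect_true(all(tl1$assignment$labels == 1L))

  # duplicating a branch cannot increase the loss, and ties go low
  model_dup <- model
  model_dup$branches[[2]] <- model_dup$branches[[1]]
  model_dup$branches[[3]] <- model_dup$branches[[1]]
  tl_dup <- total_loss(X, model_dup)
  single <- model
  single$branches <- model$branches[1]
  single$config$n_subtypes <- 1L
  expect_lte(tl_dup$loss, total_loss(X, single)$loss + 1e-12)
  expect_true(all(tl_dup$assignment$labels == 1L))
})

test_that("total loss is invariant to cell order and equivariant to branch order", {
  set.seed(12)
  X <- matrix(abs(rnorm(60)), 10, 6)
  model <- init_model(model_config(n_subtypes = 2, seed = 1), 6)
  tl <- total_loss(X, model)
  perm <- sample(10)
  tl_p <- total_loss(X[perm, ], model)
  expect_equal(tl_p$loss, tl$loss)
  expect_identical(tl_p$assignment$labels, tl$assignment$labels[perm])

  swapped <- model
  swapped$branches <- model$branches[c(2, 1)]
  tl_s <- total_loss(X, swapped)
  expect_equal(tl_s$loss, tl$loss)
  expect_identical(tl_s$assignment$labels, c(2L, 1L)[tl$assignment$labels])
})

test_that("analytic gradients match finite differences", {
  set.seed(21)
  n <- 5; m <- 7
  X <- matrix(abs(rnorm(m * n, mean = 1)), m, n)
  cfg <- model_config(n_subtypes = 1, n_res_blocks = 2, seed = 2,
                      v_init_sd = 1, init_sd = 0.5)
  model <- init_model(cfg, n)
  lam <- scdrivers:::model_lambda(model)
  st <- scdrivers:::loss_and_gradients(X, model, lam)
  g <- scdrivers:::grads_as_list(st$grads)
  params <- scdrivers:::params_as_list(model)

  loss_at <- function(params) {
    mod <- scdrivers:::set_params_from_list(model, params)
    fw <- scdrivers:::model_forward(X, mod, lam)
    mean(apply(fw$lossmat, 1, min))
  }
  eps <- 1e-6
  for (pi in seq_along(params)) {
    flat <- params[[pi]]
    probe <- seq_len(min(3, length(flat)))
    for (j in probe) {
      pp <- params
      pp[[pi]][j] <- pp[[pi]][j] + eps
      up <- loss_at(pp)
      pp[[pi]][j] <- pp[[pi]][j] - 2 * eps
      dn <- loss_at(pp)
      numeric_grad <- (up - dn) / (2 * eps)
      expect_equal(g[[pi]][j], numeric_grad, tolerance = 1e-4)
    }
  }
})

test_that("training descends and is reproducible", {
  sim <- simulate_subtypes(synthetic_scenario(m_cells = 60, n_genes = 30,
                                              seed = 4))
  cfg <- model_config(n_subtypes = 2, epochs = 120, seed = 7, n_starts = 1)
  fit <- csdgi_fit(sim$matrix, cfg)
  expect_length(fit$loss_trace, 120)
  expect_lt(mean(tail(fit$loss_trace, 30)), mean(head(fit$loss_trace, 30)))
  expect_true(all(abs(sqrt(colSums(fit$gene_weights^2)) - 1) < 1e-8))
  expect_true(all(fit$gene_weights >= 0))

  fit2 <- csdgi_fit(sim$matrix, cfg)
  expect_identical(fit$assignment$labels, fit2$assignment$labels)
  expect_identical(fit$gene_weights, fit2$gene_weights)
  expect_error(csdgi_fit(sim$matrix, model_config(n_subtypes = 100)),
               "exceeds the number of cells")
})

test_that("assign_subtypes applies the argmin and tie rules", {
  set.seed(30)
  n <- 4
  X <- matrix(abs(rnorm(20)), 5, n)
  model <- init_model(model_config(n_subtypes = 2, seed = 1), n)
  model$branches[[2]] <- model$branches[[1]]
  asg <- assign_subtypes(model, X)
  expect_true(all(asg$labels == 1L))  # exact ties -> lowest index

  # a branch that reconstructs cell 1 exactly claims it
  model2 <- init_model(model_config(n_subtypes = 2, seed = 1), n)
  model2$branches[[2]]$M <- rep(0, n)
  model2$branches[[2]]$E <- X[1, ]
  asg2 <- assign_subtypes(model2, X)
  expect_identical(asg2$labels[1], 2L)
})
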