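# Competitive low-rank residual autoencoder for subtype assignment and
# driver-gene weighting.
#
# Architecture, for a cell profile x in R^n (n genes):
#   encoder (shared):  x^{l+1} = x^l + ReLU(W^l x^l + b^l),  l = 0..p-1
#   branch k:          D = tanh(S0_k x^p), S0_k = V_k V_k' with zero diagonal
#   decoder (shared G, e; branch M_k, E_k):
#                      F = tanh(G D + e),  xhat = M_k * F + E_k  (elementwise)
#   gene weights:      lambda^k = |mu_k| / ||mu_k||_2, mu_k the left
#                      eigenvector of (I - L_k) carrying the low-rank
#                      structure, L_k = B_k^{-1} V_k V_k' (random walk on the
#                      branch's gene graph). For rank 1 this reduces to
#                      lambda^k = |V_k| / ||V_k||_2.
#   loss:              mean over cells of min_k || (x - xhat_k) * lambda^k ||^2
# Each cell is claimed by the branch with the smallest weighted loss; the
# gradient flows only through the winning branch (competitive learning) and
# lambda is treated as a constant within each step by default.

#' Model configuration
#'
#' @param n_subtypes Number of reconstruction branches (subtypes) s.
#' @param n_res_blocks Number of residual encoder blocks p (default 2).
#' @param rank Rank r of each branch's gene graph V_k V_k' (default 1, the
#'   setting used throughout; rank > 1 uses the generic eigensolver path).
#' @param epochs Full-batch training epochs (default 400).
#' @param learning_rate Adam learning rate (default 3e-3; see the methods
#'   vignette for the choice).
#' @param n_starts Number of independent restarts of the whole fit; the run
#'   with the lowest final competitive loss is kept (default 3). Restart
#'   seeds are derived deterministically from `seed`.
#' @param seed RNG seed for parameter initialization.
#' @param lambda_detached If `TRUE` (default) the gene weights are held
#'   constant within each gradient step and recomputed from V each epoch;
#'   if `FALSE` (rank 1 only) the gradient also flows through lambda.
#' @param softmin_temperature `NULL` (default) for hard winner-takes-all
#'   gradient routing; a positive number enables soft-min routing with
#'   weights softmax(-loss / temperature).
#' @param warmup_epochs Number of initial epochs during which every branch
#'   is trained on every cell before the winner-takes-all competition
#'   starts (default `round(3 * epochs / 8)`, long enough at the default
#'   learning rate for the affine read-out to absorb the gene means before
#'   branches start competing). Without a warm-up, whichever branch starts
#'   with the luckier random gene weights claims all cells in the first few
#'   epochs and the remaining branches never receive a gradient again
#'   (competitive-learning dead units).
#' @param init_sd Scale of the random encoder/decoder weight initialization
#'   (standard deviation before the 1/sqrt(n) fan-in scaling).
#' @param v_init_sd Scale of the branch factor initialization (standard
#'   deviation before the 1/sqrt(n) fan-in scaling; default 0.01). Kept
#'   small so the direction V grows into — and with it the gene-weight
#'   ranking lambda = |V| — is selected by the data during training rather
#'   than by the random draw.
#' @param branch_jitter Relative scale of the distinct random perturbation
#'   added to the shared random base direction of each branch's V at
#'   initialization (default 0.1). Branches must start distinct (or they
#'   would never specialize) but with comparable gene-weight profiles (or
#'   the initial competition is decided by initialization luck rather than
#'   by the data).
#' @param degree_guard Lower bound applied to the magnitude of the gene-graph
#'   degrees before inversion (default 1e-12).
#' @return A list of class `model_config`.
#' @export
model_config <- function(n_subtypes, n_res_blocks = 2, rank = 1, epochs = 400,
                         learning_rate = 3e-3, seed = 0, n_starts = 3,
                         lambda_detached = TRUE, softmin_temperature = NULL,
                         warmup_epochs = NULL, init_sd = 0.5,
                         v_init_sd = 0.1, branch_jitter = 0.1,
                         degree_guard = 1e-12) {
  if (n_starts < 1) stop_scdrivers("n_starts must be >= 1")
  if (n_subtypes < 1) stop_scdrivers("n_subtypes must be >= 1")
  if (n_res_blocks < 1) stop_scdrivers("n_res_blocks must be >= 1")
  if (rank < 1) stop_scdrivers("rank must be >= 1")
  if (epochs < 1) stop_scdrivers("epochs must be >= 1")
  if (learning_rate <= 0) stop_scdrivers("learning_rate must be positive")
  if (!is.null(softmin_temperature) && softmin_temperature <= 0) {
    stop_scdrivers("softmin_temperature must be positive or NULL")
  }
  if (is.null(warmup_epochs)) warmup_epochs <- round(3 * epochs / 8)
  if (warmup_epochs < 0 || warmup_epochs >= epochs) {
    stop_scdrivers("warmup_epochs must lie in [0, epochs)")
  }
  structure(list(n_subtypes = as.integer(n_subtypes),
                 n_res_blocks = as.integer(n_res_blocks),
                 rank = as.integer(rank), epochs = as.integer(epochs),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 n_starts = as.integer(n_starts),
                 lambda_detached = isTRUE(lambda_detached),
                 softmin_temperature = softmin_temperature,
                 warmup_epochs = as.integer(warmup_epochs),
                 init_sd = init_sd, v_init_sd = v_init_sd,
                 branch_jitter = branch_jitter,
                 degree_guard = degree_guard),
            class = "model_config")
}

#' Initialize model parameters
#'
#' Deterministic given `config$seed`. Encoder and decoder weights are
#' small-scale Gaussian (sd `init_sd / sqrt(n)`), biases zero; each branch's
#' V is an independent Gaussian draw (so branches start distinct), the
#' reconstruction scale M starts at ones and the bias E at zeros.
#'
#' @param config A [model_config()].
#' @param n Number of genes (>= 2).
#' @return A list with elements `encoder` (`W`, `b` lists), `decoder`
#'   (`G`, `e`) and `branches` (each with `V`, `M`, `E`), plus the config.
#' @export
init_model <- function(config, n) {
  if (n < 2) stop_scdrivers("the model needs at least 2 genes")
  sd0 <- config$init_sd / sqrt(n)
  local_seed(config$seed, {
    encoder <- list(
      W = lapply(seq_len(config$n_res_blocks),
                 function(l) matrix(stats::rnorm(n * n, sd = sd0), n, n)),
      b = lapply(seq_len(config$n_res_blocks), function(l) numeric(n)))
    decoder <- list(G = matrix(stats::rnorm(n * n, sd = 1 / sqrt(n)), n, n),
                    e = numeric(n))
    # Branch factors start small (sd v_init_sd / sqrt(n), v_init_sd << 1),
    # with a shared random base plus a small distinct jitter per branch.
    # Small-scale V matters twice: (i) the gene-weight ranking lambda = |V|
    # ends up dominated by the structure V grows into during training, not
    # by the initial random draw; (ii) all branches start with near-zero
    # propagation D and hence near-identical losses, so the winner-takes-all
    # competition opens fair instead of being decided by initialization
    # luck. Fully independent full-scale draws hand one branch a systematic
    # loss advantage over every cell, which the hard-min routing locks in
    # (dead branches).
    v_sd <- config$v_init_sd / sqrt(n)
    V_base <- matrix(stats::rnorm(n * config$rank, sd = v_sd), n,
                     config$rank)
    branches <- lapply(seq_len(config$n_subtypes), function(k) {
      V <- V_base + matrix(stats::rnorm(n * config$rank,
                                        sd = config$branch_jitter * v_sd),
                           n, config$rank)
      while (any(colSums(V != 0) == 0L)) {
        V <- V_base + matrix(stats::rnorm(n * config$rank,
                                          sd = config$branch_jitter * v_sd),
                             n, config$rank)
      }
      list(V = V, M = rep(1, n), E = numeric(n))
    })
    list(encoder = encoder, decoder = decoder, branches = branches,
         config = config)
  })
}

#' Residual encoder forward pass
#'
#' Applies the p residual blocks `x <- x + ReLU(W x + b)`; with all weights
#' zero the encoder is the identity (pure skip connections).
#'
#' @param x A length-n vector or an m x n matrix of cell profiles (rows).
#' @param encoder The `encoder` element of a model (lists `W`, `b`).
#' @return Encoded profiles with the same shape as `x`.
#' @export
encoder_forward <- function(x, encoder) {
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, 1L) else as.matrix(x)
  out <- encoder_forward_cached(X, encoder)$out
  if (vec) drop(out) else out
}

encoder_forward_cached <- function(X, encoder) {
  p <- length(encoder$W)
  m <- nrow(X)
  A <- vector("list", p + 1L)
  Z <- vector("list", p)
  A[[1L]] <- X
  for (l in seq_len(p)) {
    Z[[l]] <- A[[l]] %*% t(encoder$W[[l]]) + rep(encoder$b[[l]], each = m)
    A[[l + 1L]] <- A[[l]] + pmax(Z[[l]], 0)
  }
  list(out = A[[p + 1L]], A = A, Z = Z)
}

# Zero-diagonal similarity of a branch: S0 = V V' - diag(V V').
branch_similarity <- function(V) {
  S <- tcrossprod(V)
  diag(S) <- 0
  S
}

#' Low-rank graph propagation
#'
#' Propagates an encoded profile through the branch's gene-gene similarity
#' graph with self-loops removed: `D = tanh(S0 x)` with
#' `S0 = V V' - diag(V V')`. Output entries lie in (-1, 1).
#'
#' @param xp A length-n encoded profile or an m x n matrix of them.
#' @param branch A branch parameter list (field `V`).
#' @return Propagated profile(s), same shape as `xp`.
#' @export
lowrank_propagate <- function(xp, branch) {
  S0 <- branch_similarity(branch$V)
  if (is.null(dim(xp))) {
    drop(tanh(S0 %*% xp))
  } else {
    tanh(as.matrix(xp) %*% S0)  # S0 is symmetric
  }
}

#' Decoder forward pass
#'
#' `F = tanh(G D + e)` through the shared decoder, then the branch-specific
#' affine read-out `xhat = M * F + E` (elementwise). Reconstructions are
#' bounded: `|xhat_g| <= |M_g| + |E_g|`.
#'
#' @param D A length-n propagated profile or an m x n matrix of them.
#' @param decoder The shared decoder (`G`, `e`).
#' @param branch A branch parameter list (fields `M`, `E`).
#' @return Reconstruction(s), same shape as `D`.
#' @export
decoder_forward <- function(D, decoder, branch) {
  vec <- is.null(dim(D))
  Dm <- if (vec) matrix(D, 1L) else as.matrix(D)
  m <- nrow(Dm)
  Fm <- tanh(Dm %*% t(decoder$G) + rep(decoder$e, each = m))
  xhat <- Fm * rep(branch$M, each = m) + rep(branch$E, each = m)
  if (vec) drop(xhat) else xhat
}

#' Gene weights from a branch's low-rank graph
#'
#' Builds the random-walk graph `L = B^{-1} V V'` (B the degree matrix of
#' `V V'`, degrees guarded away from zero) and takes the left eigenvector mu
#' of `I - L` attached to its smallest-magnitude eigenvalue — the direction
#' that carries the low-rank structure rather than one of the degenerate
#' eigenvalue-1 directions. The gene weight vector is `lambda = |mu|`,
#' normalized to unit Euclidean norm (sign-free and scale-fixed, so weighted
#' losses are comparable across branches). For rank 1 this has the closed
#' form `lambda = |V| / ||V||_2`, used by default; `method = "eigen"` forces
#' the dense eigensolver.
#'
#' @param branch A branch parameter list (field `V`) or an n x r matrix V.
#' @param method `"auto"` (closed form when rank 1) or `"eigen"`.
#' @param degree_guard Minimum degree magnitude before inversion.
#' @return A list with `lambda` (non-negative, unit L2 norm) and `mu` (the
#'   signed eigenvector).
#' @export
compute_lambda <- function(branch, method = c("auto", "eigen"),
                           degree_guard = 1e-12) {
  method <- match.arg(method)
  V <- if (is.list(branch)) branch$V else branch
  V <- as.matrix(V)
  n <- nrow(V)
  if (method == "auto" && ncol(V) == 1L) {
    nrm <- sqrt(sum(V^2))
    if (nrm == 0) stop_scdrivers("V is identically zero; re-initialize")
    mu <- drop(V) / nrm
    return(list(lambda = abs(mu), mu = mu))
  }
  S <- tcrossprod(V)
  deg <- rowSums(S)
  small <- abs(deg) < degree_guard
  deg[small] <- ifelse(deg[small] == 0, degree_guard,
                       sign(deg[small]) * degree_guard)
  L <- S / deg
  A <- diag(n) - L
  eig <- eigen(t(A))
  vals <- eig$values
  if (any(abs(Im(vals)) > 1e-8)) {
    ord <- order(Mod(vals))
  } else {
    ord <- order(abs(Re(vals)))
  }
  mu <- eig$vectors[, ord[1L]]
  if (max(abs(Im(mu))) > 1e-6) {
    stop_scdrivers("degenerate gene graph (complex eigenvector); ",
                   "re-initialize the branch")
  }
  mu <- Re(mu)
  lam <- abs(mu)
  nrm <- sqrt(sum(lam^2))
  if (nrm == 0) stop_scdrivers("degenerate gene weights; re-initialize")
  list(lambda = lam / nrm, mu = mu / nrm)
}

# lambda matrix (n x K) for all branches of a model.
model_lambda <- function(model) {
  lam <- vapply(model$branches,
                function(br) compute_lambda(br)$lambda,
                numeric(nrow(as.matrix(model$branches[[1L]]$V))))
  lam <- as.matrix(lam)
  colnames(lam) <- paste0("subtype", seq_along(model$branches))
  lam
}

#' Gene-weighted reconstruction loss of one cell
#'
#' `sum_g (lambda_g (x_g - xhat_g))^2`: squared error with each gene's
#' residual scaled by its weight, so high-weight genes dominate the branch
#' competition.
#'
#' @param x,xhat,lam Numeric vectors of equal length.
#' @return A non-negative scalar.
#' @export
weighted_cell_loss <- function(x, xhat, lam) {
  if (length(x) != length(xhat) || length(x) != length(lam)) {
    stop_scdrivers("x, xhat and lam must have equal length")
  }
  sum((lam * (x - xhat))^2)
}

# Forward pass over all branches. Returns per-branch reconstructions and the
# m x K weighted loss matrix.
model_forward <- function(X, model, lam = model_lambda(model),
                          enc = encoder_forward_cached(X, model$encoder)) {
  m <- nrow(X)
  K <- length(model$branches)
  Xp <- enc$out
  branches <- vector("list", K)
  lossmat <- matrix(0, m, K)
  for (k in seq_len(K)) {
    br <- model$branches[[k]]
    S0 <- branch_similarity(br$V)
    U <- Xp %*% S0
    D <- tanh(U)
    Phi <- D %*% t(model$decoder$G) + rep(model$decoder$e, each = m)
    Fm <- tanh(Phi)
    xhat <- Fm * rep(br$M, each = m) + rep(br$E, each = m)
    lossmat[, k] <- (X - xhat)^2 %*% (lam[, k]^2)
    branches[[k]] <- list(S0 = S0, D = D, Fm = Fm, xhat = xhat)
  }
  list(enc = enc, branches = branches, lossmat = lossmat)
}

# Labels and mean min-loss from a loss matrix; ties go to the lowest index.
assignment_from_lossmat <- function(lossmat, cell_ids = NULL) {
  labels <- max.col(-lossmat, ties.method = "first")
  structure(list(labels = labels, losses = lossmat, cell_ids = cell_ids),
            class = "subtype_assignment")
}

#' Total competitive reconstruction loss
#'
#' Mean over cells of the minimum (over branches) gene-weighted
#' reconstruction loss, together with the induced per-cell subtype
#' assignment (argmin branch, ties to the lowest index).
#'
#' @param x An [expression_matrix()] or numeric matrix (cells x genes).
#' @param model A model as returned by [init_model()] or [csdgi_fit()].
#' @param lam Optional n x K gene-weight matrix; recomputed from the model's
#'   branches when missing.
#' @return A list with `loss` (scalar) and `assignment`
#'   (a `subtype_assignment`: `labels`, `losses`).
#' @export
total_loss <- function(x, model, lam = NULL) {
  X <- as.matrix(unclass(x))
  if (is.null(lam)) lam <- model_lambda(model)
  fw <- model_forward(X, model, lam)
  asg <- assignment_from_lossmat(fw$lossmat, rownames(X))
  idx <- cbind(seq_len(nrow(X)), asg$labels)
  list(loss = mean(fw$lossmat[idx]), assignment = asg)
}

# ---- training -------------------------------------------------------------

# Gradients of the competitive loss at the current parameters.
# routing: an m x K matrix of per-cell branch responsibilities (one-hot rows
# for hard min, softmax rows for soft-min routing).
model_gradients <- function(X, model, lam, fw, routing) {
  m <- nrow(X)
  n <- ncol(X)
  K <- length(model$branches)
  p <- length(model$encoder$W)
  grads <- list(
    W = lapply(seq_len(p), function(l) matrix(0, n, n)),
    b = lapply(seq_len(p), function(l) numeric(n)),
    G = matrix(0, n, n), e = numeric(n),
    V = vector("list", K), M = vector("list", K), E = vector("list", K))
  Xp <- fw$enc$out
  dXp <- matrix(0, m, n)
  for (k in seq_len(K)) {
    w <- routing[, k]
    act <- which(w > 0)
    if (length(act) == 0L) {
      br0 <- model$branches[[k]]
      grads$V[[k]] <- matrix(0, n, ncol(br0$V))
      grads$M[[k]] <- numeric(n)
      grads$E[[k]] <- numeric(n)
      next
    }
    br <- model$branches[[k]]
    cache <- fw$branches[[k]]
    Xa <- X[act, , drop = FALSE]
    wa <- w[act]
    lam2 <- lam[, k]^2
    # d(mean min loss)/d xhat on the active cells
    Gk <- (2 / m) * wa * (cache$xhat[act, , drop = FALSE] - Xa) *
      rep(lam2, each = length(act))
    Fa <- cache$Fm[act, , drop = FALSE]
    grads$M[[k]] <- colSums(Gk * Fa)
    grads$E[[k]] <- colSums(Gk)
    dF <- Gk * rep(br$M, each = length(act))
    dPhi <- dF * (1 - Fa^2)
    grads$G <- grads$G + crossprod(dPhi, cache$D[act, , drop = FALSE])
    grads$e <- grads$e + colSums(dPhi)
    dD <- dPhi %*% model$decoder$G
    dU <- dD * (1 - cache$D[act, , drop = FALSE]^2)
    dS0 <- crossprod(Xp[act, , drop = FALSE], dU)
    dXp[act, ] <- dXp[act, ] + dU %*% cache$S0  # S0 symmetric
    diag(dS0) <- 0
    grads$V[[k]] <- (dS0 + t(dS0)) %*% br$V
    if (!model$config$lambda_detached) {
      # gradient of the loss through lambda = |V|/||V|| (rank 1 only)
      if (ncol(br$V) != 1L) {
        stop_scdrivers("lambda_detached = FALSE requires rank 1")
      }
      v <- drop(br$V)
      nrm <- sqrt(sum(v^2))
      r2 <- colSums(wa * (Xa - cache$xhat[act, , drop = FALSE])^2)
      dlam <- (2 / m) * lam[, k] * r2
      # d lambda_g / d v_h = sign(v_g) delta_gh / nrm - |v_g| v_h / nrm^3
      grads$V[[k]] <- grads$V[[k]] +
        matrix(sign(v) * dlam / nrm - v * sum(abs(v) * dlam) / nrm^3,
               ncol = 1L)
    }
  }
  # back through the residual encoder
  dA <- dXp
  for (l in rev(seq_len(p))) {
    mask <- fw$enc$Z[[l]] > 0
    dH <- dA * mask
    grads$W[[l]] <- crossprod(dH, fw$enc$A[[l]])
    grads$b[[l]] <- colSums(dH)
    dA <- dA + dH %*% model$encoder$W[[l]]
  }
  grads
}

# One evaluation of loss + gradients (used by the training loop and by the
# finite-difference gradient tests). With `uniform_routing` every branch is
# trained on every cell (the warm-up regime); the reported loss is always
# the competitive min-over-branches objective.
loss_and_gradients <- function(X, model, lam, uniform_routing = FALSE) {
  fw <- model_forward(X, model, lam)
  m <- nrow(X)
  K <- ncol(fw$lossmat)
  labels <- max.col(-fw$lossmat, ties.method = "first")
  temp <- model$config$softmin_temperature
  if (uniform_routing) {
    routing <- matrix(1 / K, m, K)
    loss <- mean(fw$lossmat[cbind(seq_len(m), labels)])
  } else if (is.null(temp)) {
    routing <- matrix(0, m, K)
    routing[cbind(seq_len(m), labels)] <- 1
    loss <- mean(fw$lossmat[cbind(seq_len(m), labels)])
  } else {
    z <- -fw$lossmat / temp
    z <- z - apply(z, 1L, max)
    routing <- exp(z) / rowSums(exp(z))
    loss <- mean(rowSums(routing * fw$lossmat))
  }
  list(loss = loss, labels = labels,
       grads = model_gradients(X, model, lam, fw, routing))
}

# Flatten / restore parameters for the optimizer.
params_as_list <- function(model) {
  c(model$encoder$W, model$encoder$b, list(model$decoder$G, model$decoder$e),
    lapply(model$branches, `[[`, "V"),
    lapply(model$branches, `[[`, "M"),
    lapply(model$branches, `[[`, "E"))
}

grads_as_list <- function(grads) {
  c(grads$W, grads$b, list(grads$G, grads$e), grads$V, grads$M, grads$E)
}

set_params_from_list <- function(model, params) {
  p <- length(model$encoder$W)
  K <- length(model$branches)
  i <- 0L
  model$encoder$W <- params[i + seq_len(p)]; i <- i + p
  model$encoder$b <- params[i + seq_len(p)]; i <- i + p
  model$decoder$G <- params[[i + 1L]]
  model$decoder$e <- params[[i + 2L]]; i <- i + 2L
  for (k in seq_len(K)) model$branches[[k]]$V <- params[[i + k]]
  i <- i + K
  for (k in seq_len(K)) model$branches[[k]]$M <- params[[i + k]]
  i <- i + K
  for (k in seq_len(K)) model$branches[[k]]$E <- params[[i + k]]
  model
}

#' Fit the competitive subtype model
#'
#' Full-batch Adam minimization of the competitive reconstruction loss for
#' `config$epochs` epochs. The gene weights lambda are recomputed from the
#' current V at the start of every epoch (closed form for rank 1) and held
#' constant within the step when `config$lambda_detached`; after the
#' warm-up phase, gradients flow only through each cell's winning branch
#' unless soft-min routing is enabled. The whole optimization is restarted
#' `config$n_starts` times from different seeds (derived deterministically
#' from `config$seed`) and the run with the lowest final competitive loss
#' is returned; like any competitive/clustering objective the loss surface
#' has local minima, and restarts are the standard remedy. Deterministic
#' given the seed.
#'
#' @param x An [expression_matrix()] or numeric matrix, cells x genes.
#' @param config A [model_config()].
#' @return An object of class `csdgi_fit`: the trained `model`, the final
#'   `gene_weights` (n x K matrix), the final `assignment`
#'   (`labels`, `losses`), the per-epoch `loss_trace` of the selected run,
#'   plus `gene_names`, `cell_ids`, `config` and `selected_start`.
#' @export
csdgi_fit <- function(x, config) {
  best <- NULL
  for (start in seq_len(config$n_starts)) {
    cfg_s <- config
    cfg_s$seed <- as.integer(derive_seed(config$seed, start))
    fit <- csdgi_fit_single(x, cfg_s)
    if (is.null(best) || fit$final_loss < best$final_loss) {
      best <- fit
      best$selected_start <- start
    }
  }
  best$config <- config
  best
}

csdgi_fit_single <- function(x, config) {
  X <- as.matrix(unclass(x))
  m <- nrow(X); n <- ncol(X)
  if (config$n_subtypes > m) {
    stop_scdrivers("n_subtypes (", config$n_subtypes,
                   ") exceeds the number of cells (", m, ")")
  }
  if (n < 2) stop_scdrivers("the model needs at least 2 genes")
  model <- init_model(config, n)
  params <- params_as_list(model)
  ms <- lapply(params, function(p) p * 0)
  vs <- lapply(params, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8
  lr <- config$learning_rate
  trace <- numeric(config$epochs)
  for (epoch in seq_len(config$epochs)) {
    lam <- model_lambda(model)
    step <- loss_and_gradients(X, model, lam,
                               uniform_routing = epoch <= config$warmup_epochs)
    if (!is.finite(step$loss)) {
      stop_scdrivers("non-finite loss at epoch ", epoch,
                     "; lower learning_rate or init_sd")
    }
    trace[epoch] <- step$loss
    g <- grads_as_list(step$grads)
    for (i in seq_along(params)) {
      ms[[i]] <- beta1 * ms[[i]] + (1 - beta1) * g[[i]]
      vs[[i]] <- beta2 * vs[[i]] + (1 - beta2) * g[[i]]^2
      mhat <- ms[[i]] / (1 - beta1^epoch)
      vhat <- vs[[i]] / (1 - beta2^epoch)
      params[[i]] <- params[[i]] - lr * mhat / (sqrt(vhat) + adam_eps)
    }
    model <- set_params_from_list(model, params)
  }
  lam <- model_lambda(model)
  final <- total_loss(X, model, lam)
  rownames(lam) <- colnames(X)
  structure(list(model = model, gene_weights = lam,
                 mu = vapply(model$branches,
                             function(br) compute_lambda(br)$mu, numeric(n)),
                 assignment = final$assignment, loss_trace = trace,
                 final_loss = final$loss, gene_names = colnames(X),
                 cell_ids = rownames(X), config = config),
            class = "csdgi_fit")
}

#' @export
print.csdgi_fit <- function(x, ...) {
  cat(sprintf("csdgi_fit: %d cells, %d genes, %d subtypes\n",
              length(x$assignment$labels), length(x$gene_names),
              x$config$n_subtypes))
  cat(sprintf("  epochs: %d, final loss: %.6g\n",
              x$config$epochs, x$final_loss))
  cat("  cells per subtype:",
      paste(tabulate(x$assignment$labels, x$config$n_subtypes),
            collapse = ", "), "\n")
  invisible(x)
}

#' Assign cells to subtypes with a trained model
#'
#' Computes the gene-weighted reconstruction loss of every cell against every
#' branch and labels each cell with the argmin branch (ties to the lowest
#' index). The full per-cell, per-branch loss matrix is returned for audit.
#'
#' @param fit A `csdgi_fit` (or a bare model list from [init_model()]).
#' @param x An [expression_matrix()] or numeric matrix, cells x genes.
#' @return A `subtype_assignment`: `labels` (integer per cell), `losses`
#'   (m x K matrix), `cell_ids`.
#' @export
assign_subtypes <- function(fit, x) {
  model <- if (inherits(fit, "csdgi_fit")) fit$model else fit
  X <- as.matrix(unclass(x))
  total_loss(X, model)$assignment
}
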