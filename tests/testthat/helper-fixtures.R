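# Shared fixture builders; everything is generated in code at test time.

rand_kernel <- function(Q, variance = NULL) {
  ard_se_kernel(runif(Q, 0.4, 2), variance %||% runif(1, 0.5, 2))
}

rand_beliefs <- function(Tn, Q, var_range = c(0.05, 0.5)) {
  belief_seq(matrix(rnorm(Tn * Q), Tn, Q),
             matrix(runif(Tn * Q, var_range[1], var_range[2]), Tn, Q))
}

# Monte-Carlo estimates of the psi statistics with standard errors.
psi_mc <- function(kernel, Z, beliefs, n = 1e5) {
  Tn <- nrow(beliefs$mean)
  Q <- ncol(beliefs$mean)
  P <- nrow(Z)
  p0 <- 0
  p0_se2 <- 0
  P1 <- matrix(0, Tn, P)
  P1_se2 <- matrix(0, Tn, P)
  P2 <- matrix(0, P, P)
  P2_se2 <- matrix(0, P, P)
  for (t in seq_len(Tn)) {
    X <- matrix(rnorm(n * Q), n, Q) * rep(sqrt(beliefs$var[t, ]), each = n) +
      rep(beliefs$mean[t, ], each = n)
    Kx <- gram(kernel, X, Z)
    p0 <- p0 + kernel$variance          # k(x,x) is deterministic for ARD-SE
    P1[t, ] <- colMeans(Kx)
    P1_se2[t, ] <- apply(Kx, 2, stats::var) / n
    for (p in seq_len(P)) {
      pr <- Kx[, p] * Kx
      P2[p, ] <- P2[p, ] + colMeans(pr)
      P2_se2[p, ] <- P2_se2[p, ] + apply(pr, 2, stats::var) / n
    }
  }
  list(psi0 = p0, psi1 = P1, psi1_se = sqrt(P1_se2),
       psi2 = P2, psi2_se = sqrt(P2_se2))
}

# Exact GP log marginal likelihood by direct Cholesky, the full-capacity
# oracle for the collapsed bound.
exact_gp_logml <- function(Y, kernel, X, noise_var, jitter = 0) {
  Y <- as.matrix(Y)
  K <- gram(kernel, X) + diag(noise_var + jitter, nrow(Y))
  U <- chol(K)
  sum(apply(Y, 2, function(y) {
    a <- backsolve(U, backsolve(U, y, transpose = TRUE))
    -0.5 * sum(y * a) - sum(log(diag(U))) - 0.5 * length(y) * log(2 * pi)
  }))
}

small_synth <- function(T = 50, seed = 3, trials = 1) {
  make_synthetic_dataset(synthetic_spec(T = T, seed = seed), trials = trials)
}

small_model <- function(ts, Q = 2, dyn_ips = 4, kin_ips = 5, seed = 1,
                        order = 2) {
  init_vcgpdm(vcgpdm(ts$column_map, Q, dyn_ips, kin_ips, order), ts,
              seed = seed)
}

# Move a freshly initialized model to a generic, well-conditioned
# parameter point: PCA initialization of nearly noiseless data leaves
# Gram matrices with condition numbers ~1e9, where both the ELBO value
# and finite differences lose most of their digits.
perturb_model <- function(m, seed = 1) {
  set.seed(seed)
  for (i in seq_len(m$M)) {
    p <- m$parts[[i]]
    m$parts[[i]]$beta <- p$beta * 30
    m$parts[[i]]$latent$mean <- p$latent$mean +
      matrix(rnorm(length(p$latent$mean), sd = 0.2), nrow(p$latent$mean))
    m$parts[[i]]$latent$var[] <- runif(length(p$latent$var), 0.05, 0.3)
    m$parts[[i]]$kin_Z <- p$kin_Z +
      matrix(rnorm(length(p$kin_Z), sd = 0.3), nrow(p$kin_Z))
    for (j in seq_len(m$M)) {
      cp <- m$couplings[[i]][[j]]
      m$couplings[[i]][[j]]$inducing <- cp$inducing +
        matrix(rnorm(length(cp$inducing), sd = 0.3), nrow(cp$inducing))
    }
  }
  m
}

quick_config <- function(seed = 1, joint = 60, block = 30, cycles = 1) {
  training_config(max_joint_iters = joint, max_block_iters = block,
                  max_cycles = cycles, seed = seed)
}

# Monte-Carlo estimate of the expected log product-of-experts likelihood
# for target part j under q(x) and an explicit joint Gaussian q(u):
# samples latent trajectories, inducing values and coupling-function
# values from the sparse conditionals, vectorized over samples.
dyn_loglik_mc <- function(posteriors, couplings_j, order, j, qm, Scov,
                          nmc = 1e4, jitter = 1e-6) {
  Tn <- nrow(posteriors[[1]]$mean)
  idx <- vcgpdm:::.ar_index(Tn, order, NULL)
  M <- length(posteriors)
  Qj <- ncol(posteriors[[j]]$mean)
  alphas <- vapply(couplings_j, function(cp) cp$alpha, numeric(1))
  aj <- 1 / sum(1 / alphas)
  Ps <- vapply(couplings_j, function(cp) nrow(cp$inducing), numeric(1))
  off <- cumsum(c(0, Ps))
  Kin <- lapply(couplings_j, function(cp) {
    solve(gram(cp$kernel, cp$inducing, jitter = jitter * cp$kernel$variance))
  })
  # sample latents: per part an n x Tn x Q array
  xs <- lapply(posteriors, function(p) {
    Q <- ncol(p$mean)
    a <- array(rnorm(nmc * Tn * Q), c(nmc, Tn, Q))
    for (t in seq_len(Tn)) {
      a[, t, ] <- sweep(sweep(a[, t, , drop = FALSE], 3, sqrt(p$var[t, ]),
                              "*"),
                        3, p$mean[t, ], "+")
    }
    a
  })
  # sample joint inducing values, one n x tot matrix per output dim
  cholS <- chol(Scov)
  U <- lapply(seq_len(Qj), function(q) {
    matrix(rnorm(nmc * nrow(qm)), nmc) %*% cholS +
      matrix(qm[, q], nmc, nrow(qm), byrow = TRUE)
  })
  ll <- rep(-0.5 * length(idx$target) * Qj * log(2 * pi * aj), nmc)
  for (tt in seq_along(idx$target)) {
    fm <- matrix(0, nmc, Qj)
    for (i in seq_len(M)) {
      Qi <- ncol(posteriors[[i]]$mean)
      Xin <- do.call(cbind, lapply(seq_len(order), function(l) {
        matrix(xs[[i]][, idx$lags[tt, l], ], nmc, Qi)
      }))
      cp <- couplings_j[[i]]
      kx <- gram(cp$kernel, Xin, cp$inducing)
      phi <- kx %*% Kin[[i]]
      b <- pmax(cp$kernel$variance - rowSums(kx * phi), 0)
      for (q in seq_len(Qj)) {
        Ui <- U[[q]][, off[i] + seq_len(Ps[i]), drop = FALSE]
        fm[, q] <- fm[, q] + (rowSums(phi * Ui) + rnorm(nmc) * sqrt(b)) /
          alphas[i]
      }
    }
    xt <- matrix(xs[[j]][, idx$target[tt], ], nmc, Qj)
    ll <- ll - 0.5 * rowSums((xt - aj * fm)^2) / aj
  }
  list(mean = mean(ll), se = sd(ll) / sqrt(nmc))
}

# Brute-force DTW by exhaustive enumeration of all monotone alignment
# paths, minimizing total cost and, among ties, path length.
dtw_brute <- function(A, B) {
  A <- as.matrix(A)
  B <- as.matrix(B)
  n <- nrow(A)
  m <- nrow(B)
  d <- outer(rowSums(A^2), rep(1, m)) + outer(rep(1, n), rowSums(B^2)) -
    2 * A %*% t(B)
  best <- list(cost = Inf, len = Inf)
  rec <- function(i, j, cost, len) {
    cost <- cost + d[i, j]
    len <- len + 1
    if (i == n && j == m) {
      if (cost < best$cost ||
          (cost == best$cost && len < best$len)) {
        best <<- list(cost = cost, len = len)
      }
      return(invisible(NULL))
    }
    if (i < n) rec(i + 1, j, cost, len)
    if (j < m) rec(i, j + 1, cost, len)
    if (i < n && j < m) rec(i + 1, j + 1, cost, len)
  }
  rec(1, 1, 0, 0)
  best$mse <- best$cost / best$len
  best
}

`%||%` <- function(a, b) if (is.null(a)) b else a
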