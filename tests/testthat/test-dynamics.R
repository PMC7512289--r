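test_that("poe_combine is a precision-weighted product of Gaussians", {
  expect_equal(poe_combine(list(c(1, 2)), 0.7),
               list(mean = c(1, 2), variance = 0.7))
  expect_equal(poe_combine(list(0, 2), c(1, 1)),
               list(mean = 1, variance = 0.5))
  # grid oracle: renormalized pointwise product of three Gaussian densities
  set.seed(21)
  mu <- rnorm(3)
  al <- runif(3, 0.3, 2)
  x <- seq(-10, 10, by = 1e-3)
  dens <- exp(rowSums(sapply(1:3, function(i) dnorm(x, mu[i], sqrt(al[i]),
                                                   log = TRUE))))
  dens <- dens / sum(dens * 1e-3)
  gm <- sum(x * dens * 1e-3)
  gv <- sum((x - gm)^2 * dens * 1e-3)
  pc <- poe_combine(as.list(mu), al)
  expect_equal(pc$mean, gm, tolerance = 1e-6)
  expect_equal(pc$variance, gv, tolerance = 1e-5)
  # combined variance never exceeds the sharpest expert
  expect_lte(pc$variance, min(al))
  expect_error(poe_combine(list(), numeric(0)), "one expert")
  expect_error(poe_combine(list(0, 1), c(1, -1)), "positive")
})

test_that("marginalized kernel is the alpha-weighted mean of coupling kernels", {
  set.seed(22)
  X <- matrix(rnorm(6), 3, 2)
  k1 <- rand_kernel(2); k2 <- rand_kernel(2)
  cp1 <- coupling_gp(1, 1, k1, X, alpha = 0.8)
  # single coupling: identical to the part's own dynamics kernel
  expect_equal(marginalized_kernel(list(cp1), X), gram(k1, X))
  # two couplings with equal alphas: (k1 + k2)/4
  cpa <- coupling_gp(1, 2, k1, X, alpha = 1)
  cpb <- coupling_gp(2, 2, k2, X, alpha = 1)
  expect_equal(marginalized_kernel(list(cpa, cpb), X),
               (gram(k1, X) + gram(k2, X)) / 4)
  # brute-force marginalization of the PoE mean prediction on a 3-point
  # instance: cov of W f with f ~ N(0, blockdiag(K1, K2))
  a1 <- 0.6; a2 <- 1.7
  cpa <- coupling_gp(1, 2, k1, X, alpha = a1)
  cpb <- coupling_gp(2, 2, k2, X, alpha = a2)
  X2 <- matrix(rnorm(6), 3, 2)
  aj <- 1 / (1 / a1 + 1 / a2)
  Kblk <- rbind(cbind(gram(k1, X), matrix(0, 3, 3)),
                cbind(matrix(0, 3, 3), gram(k2, X2)))
  W <- cbind(diag(3) * aj / a1, diag(3) * aj / a2)
  expect_equal(marginalized_kernel(list(cpa, cpb), list(X, X2)),
               W %*% Kblk %*% t(W))
  expect_error(marginalized_kernel(list(cpa, cp1), X), "target")
})

test_that("entropy of the factorized posterior is exact and additive", {
  expect_equal(entropy(belief_seq(matrix(0), matrix(1))),
               0.5 * log(2 * pi * exp(1)))
  set.seed(23)
  b1 <- rand_beliefs(5, 2)
  b2 <- rand_beliefs(5, 3)
  expect_equal(entropy(list(b1, b2)), entropy(b1) + entropy(b2))
  # Monte-Carlo: -E log q
  n <- 2e5
  v <- b1$var[1, 1]
  z <- rnorm(n, 0, sqrt(v))
  h_mc <- -mean(dnorm(z, 0, sqrt(v), log = TRUE))
  se <- sd(dnorm(z, 0, sqrt(v), log = TRUE)) / sqrt(n)
  expect_lt(abs(entropy(belief_seq(matrix(0), matrix(v))) - h_mc), 3 * se)
  expect_error(entropy(belief_seq(matrix(0), matrix(0))), "positive")
})

test_that("initial-state term is the unit-Gaussian cross-entropy", {
  b <- belief_seq(matrix(0, 3, 2), matrix(1, 3, 2))
  # two initial states x two dims, each contributing -(1 + log 2 pi)/2
  expect_equal(initial_state_term(b, order = 2),
               4 * (-0.5 * (1 + log(2 * pi))))
  # decreases as |mu| grows
  b2 <- belief_seq(matrix(2, 3, 2), matrix(1, 3, 2))
  expect_lt(initial_state_term(b2, order = 2), initial_state_term(b, order = 2))
  # Monte-Carlo
  set.seed(24)
  mu <- 0.7; v <- 0.4
  z <- rnorm(2e5, mu, sqrt(v))
  lp <- dnorm(z, log = TRUE)
  bmc <- belief_seq(matrix(c(mu, 0), 2, 1), matrix(c(v, 1), 2, 1))
  an <- initial_state_term(bmc, order = 1, seq_id = c(1L, 2L))
  expect_lt(abs(an - (mean(lp) + dnorm(0, log = TRUE) - 0.5)),
            3 * sd(lp) / sqrt(2e5) + 1e-10)
})

make_two_part <- function(Tn = 10, Q = 1, P = 3, order = 2, seed = 25) {
  set.seed(seed)
  posteriors <- lapply(1:2, function(i) rand_beliefs(Tn, Q))
  alphas <- matrix(runif(4, 0.5, 1.5), 2, 2)
  couplings <- lapply(1:2, function(i) lapply(1:2, function(j) {
    coupling_gp(i, j, rand_kernel(order * Q, variance = 1),
                matrix(rnorm(P * order * Q), P, order * Q), alphas[i, j])
  }))
  list(posteriors = posteriors, couplings = couplings, order = order)
}

test_that("the collapsed dynamics bound equals expected log-lik minus KL at the optimum", {
  tp <- make_two_part()
  idx <- vcgpdm:::.ar_index(10, tp$order, NULL)
  arb <- lapply(tp$posteriors, vcgpdm:::.ar_beliefs, lags = idx$lags)
  for (j in 1:2) {
    st <- lapply(1:2, function(i) {
      vcgpdm:::.coupling_stats(tp$couplings[[i]][[j]], arb[[i]], 1e-6)
    })
    TM <- tp$posteriors[[j]]$mean[idx$target, , drop = FALSE]
    TV <- tp$posteriors[[j]]$var[idx$target, , drop = FALSE]
    core <- vcgpdm:::.dyn_part_core(TM, TV, st)
    qu <- vcgpdm:::.dyn_part_posterior(core)
    cps <- lapply(1:2, function(i) tp$couplings[[i]][[j]])
    ta <- vcgpdm:::.dyn_expected_loglik(TM, TV, cps, arb, qu$mean, qu$cov)
    kl <- vcgpdm:::.dyn_joint_kl(qu$mean, qu$cov, st)
    expect_equal(core$val, ta - kl, tolerance = 1e-10)
  }
})

test_that("the expected log-likelihood matches Monte-Carlo sampling", {
  tp <- make_two_part(Tn = 6, seed = 26)
  idx <- vcgpdm:::.ar_index(6, tp$order, NULL)
  arb <- lapply(tp$posteriors, vcgpdm:::.ar_beliefs, lags = idx$lags)
  j <- 2
  cps <- lapply(1:2, function(i) tp$couplings[[i]][[j]])
  TM <- tp$posteriors[[j]]$mean[idx$target, , drop = FALSE]
  TV <- tp$posteriors[[j]]$var[idx$target, , drop = FALSE]
  set.seed(27)
  L <- matrix(rnorm(36, sd = 0.2), 6, 6)
  Scov <- crossprod(L) + diag(0.05, 6)
  qm <- matrix(rnorm(6), 6, 1)
  an <- vcgpdm:::.dyn_expected_loglik(TM, TV, cps, arb, qm, Scov)
  mc <- dyn_loglik_mc(tp$posteriors, cps, tp$order, j, qm, Scov, nmc = 3e4)
  expect_lt(abs(an - mc$mean), 3 * mc$se)
})

test_that("severing a coupling by a huge alpha removes its influence", {
  tp <- make_two_part(seed = 28)
  # make alpha^{2,1} huge: part 2 cannot influence part 1
  cp21 <- tp$couplings[[2]][[1]]
  tp$couplings[[2]][[1]] <- coupling_gp(2, 1, cp21$kernel, cp21$inducing, 1e8)
  idx <- vcgpdm:::.ar_index(10, 2, NULL)
  arb <- lapply(tp$posteriors, vcgpdm:::.ar_beliefs, lags = idx$lags)
  TM <- tp$posteriors[[1]]$mean[idx$target, , drop = FALSE]
  TV <- tp$posteriors[[1]]$var[idx$target, , drop = FALSE]
  st2 <- lapply(1:2, function(i) {
    vcgpdm:::.coupling_stats(tp$couplings[[i]][[1]], arb[[i]], 1e-6)
  })
  both <- vcgpdm:::.dyn_part_core(TM, TV, st2)$val
  alone <- vcgpdm:::.dyn_part_core(TM, TV, st2[1])$val
  expect_lt(abs(both - alone) / abs(alone), 1e-4)
})

test_that("the dynamics bound is invariant to relabeling parts", {
  tp <- make_two_part(seed = 29)
  v12 <- dynamics_bound(tp$posteriors, tp$couplings, order = 2)
  # swap part labels everywhere
  cps <- lapply(1:2, function(i) lapply(1:2, function(j) {
    cp <- tp$couplings[[3 - i]][[3 - j]]
    coupling_gp(i, j, cp$kernel, cp$inducing, cp$alpha)
  }))
  v21 <- dynamics_bound(rev(tp$posteriors), cps, order = 2)
  expect_equal(v12, v21, tolerance = 1e-12)
})

test_that("dynamics bound errors on sequences shorter than the order", {
  tp <- make_two_part(Tn = 2, seed = 30)
  expect_error(dynamics_bound(tp$posteriors, tp$couplings, order = 2),
               "order")
})
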