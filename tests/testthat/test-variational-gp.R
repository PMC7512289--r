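test_that("collapsed bound is exact at full capacity and a lower bound otherwise", {
  set.seed(11)
  Tn <- 25; Q <- 2; D <- 3
  k <- rand_kernel(Q)
  X <- matrix(rnorm(Tn * Q), Tn, Q)
  Y <- matrix(rnorm(Tn * D), Tn, D)
  beta <- 0.25
  exact <- exact_gp_logml(Y, k, X, beta)
  b <- collapsed_bound(Y, k, X, belief_seq(X, 0), beta, jitter = 1e-10)
  expect_lt(abs(b - exact) / abs(exact), 1e-6)
  for (rep in 1:5) {
    Zs <- X[sample(Tn, 5), , drop = FALSE]
    expect_lte(collapsed_bound(Y, k, Zs, belief_seq(X, 0), beta), exact + 1e-8)
  }
})

test_that("duplicating target columns doubles the bound", {
  set.seed(12)
  k <- rand_kernel(2)
  X <- matrix(rnorm(30), 15, 2)
  Y <- matrix(rnorm(30), 15, 2)
  b <- rand_beliefs(15, 2)
  Z <- X[1:5, ]
  expect_equal(collapsed_bound(cbind(Y, Y), k, Z, b, 0.4),
               2 * collapsed_bound(Y, k, Z, b, 0.4))
})

test_that("optimal inducing posterior attains the collapsed bound", {
  set.seed(13)
  Tn <- 20; Q <- 2; D <- 2
  k <- rand_kernel(Q)
  Y <- matrix(rnorm(Tn * D), Tn, D)
  b <- rand_beliefs(Tn, Q)
  Z <- matrix(rnorm(5 * Q), 5, Q)
  beta <- 0.3
  post <- optimal_inducing_posterior(Y, k, Z, b, beta)
  expect_equal(post$cov, t(post$cov))
  expect_true(min(eigen(post$cov, symmetric = TRUE,
                        only.values = TRUE)$values) >= -1e-10)
  cb <- collapsed_bound(Y, k, Z, b, beta)
  ub <- vcgpdm:::.uncollapsed_bound(Y, k, Z, b, beta, post$mean, post$cov)
  expect_lt(abs(cb - ub) / abs(cb), 1e-6)
  # a perturbed q(u) can only do worse
  worse <- vcgpdm:::.uncollapsed_bound(Y, k, Z, b, beta,
                                       post$mean + 0.1, post$cov)
  expect_lt(worse, cb)
})

test_that("posterior reverts to the prior in the no-information limit", {
  set.seed(14)
  k <- rand_kernel(2)
  Y <- matrix(rnorm(20), 10, 2)
  b <- rand_beliefs(10, 2)
  Z <- matrix(rnorm(8), 4, 2)
  post <- optimal_inducing_posterior(Y, k, Z, b, 1e12)
  expect_equal(max(abs(post$mean)), 0, tolerance = 1e-8)
  expect_equal(post$cov, gram(k, Z, jitter = 1e-6 * k$variance),
               tolerance = 1e-8)
})

test_that("sparse prediction interpolates and matches the exact GP", {
  set.seed(15)
  Tn <- 15; Q <- 2; D <- 2
  k <- rand_kernel(Q)
  X <- matrix(rnorm(Tn * Q), Tn, Q)
  # smooth targets (a GP draw), so near-interpolation is attainable
  Y <- crossprod(chol(gram(k, X) + diag(1e-8, Tn)), matrix(rnorm(Tn * D), Tn))
  beta <- 1e-4
  post <- optimal_inducing_posterior(Y, k, X, belief_seq(X, 0), beta,
                                     jitter = 1e-10)
  pr <- sparse_predict(X, k, X, post, jitter = 1e-10)
  exact_mean <- gram(k, X) %*% solve(gram(k, X) + diag(beta, Tn), Y)
  expect_equal(pr$mean, exact_mean, tolerance = 1e-4)
  # tiny noise: posterior mean interpolates the targets at the inputs
  expect_equal(max(abs(pr$mean - Y)), 0, tolerance = 0.05)
  expect_true(all(pr$var >= 0))
  # belief input with zero variance agrees with the point path
  prb <- sparse_predict(belief_seq(X, 0), k, X, post, jitter = 1e-10)
  expect_equal(prb$mean, pr$mean, tolerance = 1e-8)
})

test_that("the bound is invariant to time permutation and obeys scaling", {
  set.seed(16)
  Tn <- 12
  k <- rand_kernel(2)
  Y <- matrix(rnorm(Tn * 2), Tn, 2)
  b <- rand_beliefs(Tn, 2)
  Z <- matrix(rnorm(8), 4, 2)
  prm <- sample(Tn)
  b2 <- belief_seq(b$mean[prm, ], b$var[prm, ])
  expect_equal(collapsed_bound(Y, k, Z, b, 0.5),
               collapsed_bound(Y[prm, ], k, Z, b2, 0.5))
  # rescaling targets, noise sd and signal sd by c shifts by -T D log c
  cs <- 2.3
  k2 <- ard_se_kernel(k$lengthscales, k$variance * cs^2)
  expect_equal(collapsed_bound(Y * cs, k2, Z, b, 0.5 * cs^2),
               collapsed_bound(Y, k, Z, b, 0.5) - Tn * 2 * log(cs),
               tolerance = 1e-8)
})

test_that("the bound is monotone in inducing-set capacity", {
  set.seed(17)
  Tn <- 20
  k <- rand_kernel(2)
  Y <- matrix(rnorm(Tn), Tn, 1)
  b <- rand_beliefs(Tn, 2)
  X <- matrix(rnorm(Tn * 2), Tn, 2)
  for (rep in 1:5) {
    rows <- sample(Tn, 8)
    small <- collapsed_bound(Y, k, X[rows[1:4], ], b, 0.4)
    big <- collapsed_bound(Y, k, X[rows, ], b, 0.4)
    expect_gte(big, small - 1e-8)
  }
})

test_that("collapsed-bound gradients agree with finite differences", {
  set.seed(18)
  Tn <- 8; Q <- 2; P <- 3; D <- 2
  k <- rand_kernel(Q)
  Y <- matrix(rnorm(Tn * D), Tn, D)
  b <- rand_beliefs(Tn, Q)
  Z <- matrix(rnorm(P * Q), P, Q)
  beta <- 0.35
  g <- vcgpdm:::.collapsed_bound_grad(Y, k, Z, b, beta)
  an <- c(g$lengthscales, g$variance, g$noise, c(g$Z), c(g$mean), c(g$var),
          c(g$targets))
  pack <- c(k$lengthscales, k$variance, beta, c(Z), c(b$mean), c(b$var), c(Y))
  fd <- vapply(seq_along(pack), function(i) {
    e <- 1e-6 * max(abs(pack[i]), 1)
    pp <- pack; pp[i] <- pp[i] + e
    pm <- pack; pm[i] <- pm[i] - e
    f <- function(par) {
      kk <- ard_se_kernel(par[1:Q], par[Q + 1])
      ZZ <- matrix(par[Q + 2 + 1:(P * Q)], P, Q)
      bb <- belief_seq(matrix(par[Q + 2 + P * Q + 1:(Tn * Q)], Tn, Q),
                       matrix(par[Q + 2 + P * Q + Tn * Q + 1:(Tn * Q)], Tn, Q))
      YY <- matrix(par[Q + 2 + P * Q + 2 * Tn * Q + 1:(Tn * D)], Tn, D)
      collapsed_bound(YY, kk, ZZ, bb, par[Q + 2])
    }
    (f(pp) - f(pm)) / (2 * e)
  }, numeric(1))
  expect_lt(max(abs(fd - an) / pmax(abs(fd), 1e-5)), 1e-4)
})
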