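test_that("gram evaluates the ARD-SE formula and validates inputs", {
  k <- ard_se_kernel(c(1, 2), variance = 1.5)
  set.seed(1)
  X <- matrix(rnorm(10), 5, 2)
  K <- gram(k, X)
  expect_equal(diag(K), rep(1.5, 5))
  expect_equal(K, t(K))
  # 1-D unit lengthscale at distance 1
  k1 <- ard_se_kernel(1)
  expect_equal(gram(k1, matrix(0), matrix(1))[1, 1], exp(-0.5))
  # PSD up to explicit jitter
  ev <- eigen(gram(k, X) + diag(1e-8, 5), symmetric = TRUE,
              only.values = TRUE)$values
  expect_true(min(ev) >= 0)
  expect_error(gram(k, matrix(0, 2, 3)), "dimension")
  expect_error(ard_se_kernel(c(1, -1)), "positive")
  expect_error(ard_se_kernel(1, variance = 0), "positive")
})

test_that("psi0 depends only on T and the signal variance", {
  set.seed(2)
  k <- rand_kernel(3)
  b1 <- rand_beliefs(7, 3)
  b2 <- rand_beliefs(7, 3, var_range = c(0, 0))
  expect_equal(psi0(k, b1), 7 * k$variance)
  expect_equal(psi0(k, b2), psi0(k, b1))
  expect_equal(psi0(k, b2), sum(diag(gram(k, b2$mean))))
})

test_that("psi1 and psi2 reduce to plain kernel evaluations for point masses", {
  set.seed(3)
  for (rep in 1:3) {
    Q <- sample(1:3, 1)
    k <- rand_kernel(Q)
    Z <- matrix(rnorm(4 * Q), 4, Q)
    mu <- matrix(rnorm(6 * Q), 6, Q)
    b <- belief_seq(mu, 1e-12)
    Kmz <- gram(k, mu, Z)
    expect_equal(psi1(k, Z, b), Kmz, tolerance = 1e-8)
    expect_equal(psi2(k, Z, b), crossprod(Kmz), tolerance = 1e-8)
  }
})

test_that("psi1 matches the analytic 1-D Gaussian integral", {
  k <- ard_se_kernel(1)
  b <- belief_seq(matrix(0), matrix(1))
  expect_equal(psi1(k, matrix(0), b)[1, 1], sqrt(0.5), tolerance = 1e-12)
})

test_that("psi statistics match Monte-Carlo expectations within 3 s.e.", {
  set.seed(4)
  for (rep in 1:2) {
    Q <- 2
    k <- rand_kernel(Q)
    Z <- matrix(rnorm(3 * Q), 3, Q)
    b <- rand_beliefs(3, Q)
    mc <- psi_mc(k, Z, b, n = 2e5)
    expect_equal(psi0(k, b), mc$psi0)
    expect_true(all(abs(psi1(k, Z, b) - mc$psi1) <= 3 * mc$psi1_se))
    expect_true(all(abs(psi2(k, Z, b) - mc$psi2) <= 3 * mc$psi2_se))
  }
})

test_that("psi2 is symmetric and positive semi-definite", {
  set.seed(5)
  k <- rand_kernel(2)
  Z <- matrix(rnorm(10), 5, 2)
  b <- rand_beliefs(8, 2)
  P2 <- psi2(k, Z, b)
  expect_equal(P2, t(P2))
  expect_true(min(eigen(P2, symmetric = TRUE, only.values = TRUE)$values) >=
                -1e-10)
  # per-time slices sum to the total
  expect_equal(apply(psi2(k, Z, b, by_time = TRUE), c(2, 3), sum), P2)
})

test_that("psi and Gram adjoints agree with finite differences", {
  set.seed(6)
  for (rep in 1:2) {
    Tn <- 4; P <- 3; Q <- 2
    k <- rand_kernel(Q)
    Z <- matrix(rnorm(P * Q), P, Q)
    b <- rand_beliefs(Tn, Q)
    pack <- c(k$lengthscales, k$variance, c(Z), c(b$mean), c(b$var))
    unpack <- function(par) {
      list(k = ard_se_kernel(par[1:Q], par[Q + 1]),
           Z = matrix(par[Q + 1 + 1:(P * Q)], P, Q),
           b = belief_seq(matrix(par[Q + 1 + P * Q + 1:(Tn * Q)], Tn, Q),
                          matrix(par[Q + 1 + P * Q + Tn * Q + 1:(Tn * Q)],
                                 Tn, Q)))
    }
    fd_grad <- function(f) {
      vapply(seq_along(pack), function(i) {
        e <- 1e-6
        pp <- pack; pp[i] <- pp[i] + e
        pm <- pack; pm[i] <- pm[i] - e
        (f(unpack(pp)) - f(unpack(pm))) / (2 * e)
      }, numeric(1))
    }
    G1 <- matrix(rnorm(Tn * P), Tn, P)
    v1 <- vcgpdm:::.psi1_vjp(k, Z, b, G1)
    an1 <- c(v1$lengthscales, v1$variance, c(v1$Z), c(v1$mean), c(v1$var))
    fd1 <- fd_grad(function(s) sum(G1 * psi1(s$k, s$Z, s$b)))
    expect_lt(max(abs(fd1 - an1) / pmax(abs(fd1), 1e-6)), 1e-4)
    G2 <- matrix(rnorm(P * P), P, P)
    v2 <- vcgpdm:::.psi2_vjp(k, Z, b, G2)
    an2 <- c(v2$lengthscales, v2$variance, c(v2$Z), c(v2$mean), c(v2$var))
    fd2 <- fd_grad(function(s) sum(G2 * psi2(s$k, s$Z, s$b)))
    expect_lt(max(abs(fd2 - an2) / pmax(abs(fd2), 1e-6)), 1e-4)
    G3 <- matrix(rnorm(P * P), P, P)
    v3 <- vcgpdm:::.gram_vjp(k, Z, G3, 1e-6)
    an3 <- c(v3$lengthscales, v3$variance, c(v3$Z))
    fd3 <- fd_grad(function(s) {
      sum(G3 * gram(s$k, s$Z, jitter = 1e-6 * s$k$variance))
    })[1:(Q + 1 + P * Q)]
    expect_lt(max(abs(fd3 - an3) / pmax(abs(fd3), 1e-6)), 1e-4)
  }
})
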