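# Sparse inducing-point GP machinery: the collapsed variational bound for a
# GP layer with uncertain (Gaussian-belief) inputs, the closed-form optimal
# posterior over inducing values, and sparse prediction.  Used both for the
# kinematics mapping (latent -> observed) and, through the dynamics module,
# for the coupled latent transitions.

.DEFAULT_JITTER <- 1e-6

# Cholesky with escalating symmetric jitter (1e-6 -> 1e-4 of mean diagonal).
.safe_chol <- function(A) {
  U <- tryCatch(chol(A), error = function(e) NULL)
  if (!is.null(U)) return(U)
  scale <- mean(diag(A))
  for (j in c(1e-6, 1e-5, 1e-4)) {
    U <- tryCatch(chol(A + diag(j * scale, nrow(A))), error = function(e) NULL)
    if (!is.null(U)) return(U)
  }
  stop("matrix not positive definite after jitter escalation")
}

.logdet_chol <- function(U) 2 * sum(log(diag(U)))

# Core collapsed-bound computation from precomputed psi statistics.
# Returns the bound plus the intermediates needed for gradients and for the
# optimal inducing posterior.  Notation: K = inducing Gram (jittered),
# A = K + Psi2/beta, E = Psi1' Y.
.titsias_core <- function(Y, Kuu, p0, P1, P2, beta) {
  Tn <- nrow(Y)
  D <- ncol(Y)
  A <- Kuu + P2 / beta
  cU <- .safe_chol(A)
  cK <- .safe_chol(Kuu)
  E <- crossprod(P1, Y)                      # P x D
  CE <- chol2inv(cU) %*% E                   # A^{-1} E
  Kinv <- chol2inv(cK)
  trKinvP2 <- sum(Kinv * P2)
  quad <- sum(E * CE)
  bound <- D * (-0.5 * Tn * log(2 * pi) - 0.5 * Tn * log(beta) +
                  0.5 * .logdet_chol(cK) - 0.5 * .logdet_chol(cU)) -
    0.5 * sum(Y * Y) / beta + 0.5 * quad / beta^2 -
    0.5 * D * (p0 - trKinvP2) / beta
  list(bound = bound, A = A, cU = cU, cK = cK, E = E, CE = CE, Kinv = Kinv,
       trKinvP2 = trKinvP2, quad = quad, Tn = Tn, D = D)
}

#' Collapsed variational bound for a sparse GP layer with uncertain inputs
#'
#' Computes the collapsed lower bound on the log marginal likelihood
#' \eqn{\sum_d \log p(y_d)} of a GP regression whose inputs are known only
#' through a sequence of diagonal-Gaussian beliefs.  The optimal Gaussian
#' posterior over inducing values is integrated out analytically, so the
#' bound depends on the inputs only through the psi statistics.  With
#' point-mass beliefs and inducing locations equal to the inputs it equals
#' the exact GP log marginal likelihood; with fewer inducing points it is a
#' lower bound.
#'
#' @param targets numeric matrix \code{T x D} of regression targets
#'   (independent output columns, shared kernel and noise).
#' @param kernel an \code{\link{ard_se_kernel}}.
#' @param inducing matrix \code{P x Q} of inducing point locations.
#' @param beliefs a \code{\link{belief_seq}} over the \code{T} inputs.
#' @param noise_variance positive observation noise variance.
#' @param jitter diagonal jitter added to the inducing Gram matrix, as a
#'   fraction of the signal variance.
#' @return scalar lower bound.
#' @export
collapsed_bound <- function(targets, kernel, inducing, beliefs,
                            noise_variance, jitter = .DEFAULT_JITTER) {
  targets <- as.matrix(targets)
  if (!all(is.finite(targets))) stop("targets must be finite")
  if (noise_variance <= 0) stop("noise_variance must be positive")
  if (nrow(targets) != nrow(beliefs$mean)) {
    stop("targets and beliefs disagree on the number of time steps")
  }
  Z <- as.matrix(inducing)
  Kuu <- gram(kernel, Z, jitter = jitter * kernel$variance)
  .titsias_core(targets, Kuu, psi0(kernel, beliefs),
                psi1(kernel, Z, beliefs), psi2(kernel, Z, beliefs),
                noise_variance)$bound
}

# Value and full gradient of the collapsed bound with respect to kernel
# parameters, inducing locations, noise variance, belief moments and (for
# the latent-dynamics use) the targets themselves.
.collapsed_bound_grad <- function(Y, kernel, Z, beliefs, beta,
                                  jitter = .DEFAULT_JITTER) {
  Z <- as.matrix(Z)
  Kuu <- gram(kernel, Z, jitter = jitter * kernel$variance)
  p0 <- psi0(kernel, beliefs)
  P1 <- psi1(kernel, Z, beliefs)
  P2 <- psi2(kernel, Z, beliefs)
  cc <- .titsias_core(Y, Kuu, p0, P1, P2, beta)
  D <- cc$D
  Tn <- cc$Tn
  Ainv <- chol2inv(cc$cU)
  CECEt <- tcrossprod(cc$CE)                 # A^{-1} E E' A^{-1}
  KiP2Ki <- cc$Kinv %*% P2 %*% cc$Kinv
  d_K <- 0.5 * D * cc$Kinv - 0.5 * D * Ainv - 0.5 * CECEt / beta^2 -
    0.5 * D * KiP2Ki / beta
  d_P2 <- (-0.5 * D * Ainv - 0.5 * CECEt / beta^2) / beta + 0.5 * D * cc$Kinv / beta
  d_P1 <- Y %*% t(cc$CE) / beta^2
  d_p0 <- -0.5 * D / beta
  P2CE <- P2 %*% cc$CE
  d_beta <- -0.5 * Tn * D / beta + 0.5 * sum(Y * Y) / beta^2 -
    sum(cc$E * cc$CE) / beta^3 + 0.5 * sum(cc$CE * P2CE) / beta^4 +
    0.5 * D * sum(Ainv * P2) / beta^2 + 0.5 * D * (p0 - cc$trKinvP2) / beta^2
  d_Y <- -Y / beta + P1 %*% cc$CE / beta^2
  v1 <- .psi1_vjp(kernel, Z, beliefs, d_P1)
  v2 <- .psi2_vjp(kernel, Z, beliefs, d_P2)
  vk <- .gram_vjp(kernel, Z, d_K, jitter)
  list(bound = cc$bound,
       mean = v1$mean + v2$mean,
       var = v1$var + v2$var,
       lengthscales = v1$lengthscales + v2$lengthscales + vk$lengthscales,
       variance = v1$variance + v2$variance + vk$variance + d_p0 * Tn,
       Z = v1$Z + v2$Z + vk$Z,
       noise = d_beta,
       targets = d_Y,
       core = cc, P1 = P1, P2 = P2, Kuu = Kuu)
}

#' Optimal Gaussian posterior over inducing values
#'
#' The free-form posterior \eqn{q(u)} that attains the collapsed bound, in
#' closed form: mean \eqn{\beta^{-1} K (K + \beta^{-1}\Psi_2)^{-1} \Psi_1' Y}
#' per output column and a single shared covariance
#' \eqn{K (K + \beta^{-1}\Psi_2)^{-1} K}.  As the noise variance grows the
#' posterior reverts to the prior (zero mean, covariance \eqn{K}).
#'
#' @inheritParams collapsed_bound
#' @return list with elements \code{mean} (\code{P x D}) and
#'   \code{cov} (\code{P x P}).
#' @export
optimal_inducing_posterior <- function(targets, kernel, inducing, beliefs,
                                       noise_variance,
                                       jitter = .DEFAULT_JITTER) {
  targets <- as.matrix(targets)
  Z <- as.matrix(inducing)
  Kuu <- gram(kernel, Z, jitter = jitter * kernel$variance)
  P1 <- psi1(kernel, Z, beliefs)
  P2 <- psi2(kernel, Z, beliefs)
  A <- Kuu + P2 / noise_variance
  cU <- .safe_chol(A)
  AiK <- chol2inv(cU) %*% Kuu
  m <- t(AiK) %*% crossprod(P1, targets) / noise_variance
  S <- Kuu %*% AiK
  S <- (S + t(S)) / 2
  list(mean = m, cov = S)
}

# Un-collapsed free energy of the GP layer for an explicit Gaussian q(u):
# expected log-likelihood under q(x) q(u) p(g | u, x) minus KL(q(u) || p(u)).
# At the optimal q(u) this reproduces collapsed_bound; used as a
# correctness check.
.uncollapsed_bound <- function(Y, kernel, Z, beliefs, beta, q_mean, q_cov,
                               jitter = .DEFAULT_JITTER) {
  Y <- as.matrix(Y)
  Z <- as.matrix(Z)
  Tn <- nrow(Y)
  D <- ncol(Y)
  Kuu <- gram(kernel, Z, jitter = jitter * kernel$variance)
  cK <- .safe_chol(Kuu)
  Kinv <- chol2inv(cK)
  p0 <- psi0(kernel, beliefs)
  P1 <- psi1(kernel, Z, beliefs)
  P2 <- psi2(kernel, Z, beliefs)
  KiP2Ki <- Kinv %*% P2 %*% Kinv
  Mu <- P1 %*% Kinv %*% q_mean              # T x D expected g
  ell <- -0.5 * Tn * D * log(2 * pi * beta) -
    0.5 * (sum(Y * Y) - 2 * sum(Y * Mu)) / beta -
    0.5 * (sum(q_mean * (KiP2Ki %*% q_mean)) + D * sum(KiP2Ki * q_cov)) / beta -
    0.5 * D * (p0 - sum(Kinv * P2)) / beta
  cS <- .safe_chol(q_cov)
  kl <- 0.5 * D * (sum(Kinv * q_cov) - nrow(Z) +
                     .logdet_chol(cK) - .logdet_chol(cS)) +
    0.5 * sum(q_mean * (Kinv %*% q_mean))
  ell - kl
}

#' Sparse GP prediction from an inducing posterior
#'
#' Predictive mean and variance of a GP layer at new inputs, given the
#' inducing locations and a Gaussian posterior over inducing values.  For
#' point inputs this is standard sparse GP prediction; for Gaussian-belief
#' inputs the predictive mean is moment-matched through the smoothed kernel
#' expectation (psi1).
#'
#' @param x_star point matrix of new inputs (one per row), or a
#'   \code{\link{belief_seq}}.
#' @param kernel an \code{\link{ard_se_kernel}}.
#' @param inducing matrix of inducing locations.
#' @param posterior list with \code{mean} (\code{P x D}) and optional
#'   \code{cov} (\code{P x P}), as returned by
#'   \code{\link{optimal_inducing_posterior}}.
#' @param jitter Gram-matrix jitter as a fraction of the signal variance.
#' @return list with \code{mean} (\code{n x D}) and, for point inputs,
#'   \code{var} (\code{n}-vector of predictive variances, shared across
#'   output columns; excludes observation noise).
#' @export
sparse_predict <- function(x_star, kernel, inducing, posterior,
                           jitter = .DEFAULT_JITTER) {
  Z <- as.matrix(inducing)
  Kuu <- gram(kernel, Z, jitter = jitter * kernel$variance)
  cK <- .safe_chol(Kuu)
  Kinv <- chol2inv(cK)
  if (inherits(x_star, "belief_seq")) {
    Ks <- psi1(kernel, Z, x_star)
    return(list(mean = Ks %*% Kinv %*% posterior$mean))
  }
  X <- as.matrix(x_star)
  Ks <- gram(kernel, X, Z)
  KsKi <- Ks %*% Kinv
  mean <- KsKi %*% posterior$mean
  vr <- kernel$variance - rowSums(KsKi * Ks)
  if (!is.null(posterior$cov)) {
    vr <- vr + rowSums((KsKi %*% posterior$cov) * KsKi)
  }
  list(mean = mean, var = pmax(vr, 0))
}
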