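#' ARD squared-exponential kernel
#'
#' Constructs an automatic-relevance-determination squared-exponential
#' (RBF) kernel
#' \deqn{k(a, b) = v \exp\left(-\tfrac12 \sum_q (a_q - b_q)^2 / \lambda_q\right)}
#' where \eqn{\lambda_q} are per-coordinate squared lengthscales and
#' \eqn{v} the signal variance.  A large \eqn{\lambda_q} effectively
#' switches coordinate \eqn{q} off, which is how latent dimensions and
#' coupling inputs are pruned during learning.
#'
#' @param lengthscales positive numeric vector of squared lengthscales
#'   \eqn{\lambda_q}, one per input coordinate.
#' @param variance positive signal variance \eqn{v}.  The dynamics and
#'   coupling kernels use the default \code{1}; the kinematics kernel
#'   learns it so observed outputs need not be normalized.
#' @return an object of class \code{"ard_se_kernel"}.
#' @export
ard_se_kernel <- function(lengthscales, variance = 1) {
  lengthscales <- as.numeric(lengthscales)
  if (length(lengthscales) < 1L || !all(is.finite(lengthscales)) ||
      any(lengthscales <= 0)) {
    stop("lengthscales must be strictly positive and finite")
  }
  if (length(variance) != 1L || !is.finite(variance) || variance <= 0) {
    stop("variance must be a single positive finite number")
  }
  structure(list(lengthscales = lengthscales, variance = variance),
            class = "ard_se_kernel")
}

#' @export
print.ard_se_kernel <- function(x, ...) {
  cat("ARD squared-exponential kernel\n")
  cat("  squared lengthscales:", format(x$lengthscales, digits = 4), "\n")
  cat("  signal variance:     ", format(x$variance, digits = 4), "\n")
  invisible(x)
}

#' Kernel Gram matrix
#'
#' Evaluates the kernel on all pairs of rows of \code{A} and \code{B}.
#'
#' @param kernel an \code{\link{ard_se_kernel}}.
#' @param A,B point matrices with one point per row; the column count
#'   must equal the number of kernel lengthscales.
#' @param jitter nonnegative value added to the diagonal (only valid for
#'   square results), used to stabilize Cholesky factorizations.
#' @return numeric matrix \code{nrow(A) x nrow(B)}.
#' @export
gram <- function(kernel, A, B = A, jitter = 0) {
  A <- as.matrix(A)
  B <- as.matrix(B)
  lam <- kernel$lengthscales
  if (ncol(A) != length(lam) || ncol(B) != length(lam)) {
    stop("point dimension does not match the number of kernel lengthscales")
  }
  E <- matrix(0, nrow(A), nrow(B))
  for (q in seq_along(lam)) {
    E <- E + outer(A[, q], B[, q], "-")^2 / lam[q]
  }
  K <- kernel$variance * exp(-0.5 * E)
  if (jitter > 0) {
    if (nrow(K) != ncol(K)) stop("jitter requires a square Gram matrix")
    K <- K + diag(jitter, nrow(K))
  }
  K
}

#' Sequence of diagonal-Gaussian beliefs over kernel inputs
#'
#' Container for a factorized Gaussian posterior over a trajectory of
#' kernel inputs: one independent Gaussian per time step and coordinate.
#' Zero variance denotes a point mass.
#'
#' @param mean numeric matrix \code{T x Q} of means.
#' @param var numeric matrix \code{T x Q} of nonnegative variances
#'   (recycled from a scalar).
#' @return an object of class \code{"belief_seq"}.
#' @export
belief_seq <- function(mean, var = 0) {
  mean <- as.matrix(mean)
  if (length(var) == 1L) var <- matrix(var, nrow(mean), ncol(mean))
  var <- as.matrix(var)
  if (!identical(dim(mean), dim(var))) {
    stop("mean and var must have identical dimensions")
  }
  if (!all(is.finite(mean)) || !all(is.finite(var)) || any(var < 0)) {
    stop("belief means must be finite and variances finite and >= 0")
  }
  structure(list(mean = mean, var = var), class = "belief_seq")
}

.check_beliefs <- function(kernel, beliefs) {
  if (ncol(beliefs$mean) != length(kernel$lengthscales)) {
    stop("belief dimension does not match the number of kernel lengthscales")
  }
}

#' Psi statistics: expected kernel quantities under Gaussian beliefs
#'
#' Closed-form expectations of kernel entries under a sequence of
#' diagonal-Gaussian input beliefs, the building blocks of every
#' collapsed bound term:
#' \itemize{
#'   \item \code{psi0}: \eqn{\sum_t E_{q(x_t)}[k(x_t, x_t)]}, which for
#'     the stationary ARD-SE kernel is simply \eqn{T v};
#'   \item \code{psi1}: the \code{T x P} matrix
#'     \eqn{\Psi_1[t,p] = E_{q(x_t)}[k(x_t, z_p)]};
#'   \item \code{psi2}: the \code{P x P} matrix
#'     \eqn{\Psi_2[p,p'] = \sum_t E_{q(x_t)}[k(x_t,z_p) k(x_t,z_{p'})]},
#'     symmetric positive semi-definite.
#' }
#'
#' @param kernel an \code{\link{ard_se_kernel}}.
#' @param inducing matrix of inducing point locations, one per row.
#' @param beliefs a \code{\link{belief_seq}}.
#' @return \code{psi0}: scalar; \code{psi1}: \code{T x P} matrix;
#'   \code{psi2}: \code{P x P} matrix.
#' @name psi-statistics
NULL

#' @rdname psi-statistics
#' @export
psi0 <- function(kernel, beliefs) {
  .check_beliefs(kernel, beliefs)
  nrow(beliefs$mean) * kernel$variance
}

#' @rdname psi-statistics
#' @export
psi1 <- function(kernel, inducing, beliefs) {
  .check_beliefs(kernel, beliefs)
  Z <- as.matrix(inducing)
  lam <- kernel$lengthscales
  if (ncol(Z) != length(lam)) {
    stop("inducing dimension does not match the number of kernel lengthscales")
  }
  M <- beliefs$mean
  S <- beliefs$var
  L <- matrix(log(kernel$variance), nrow(M), nrow(Z))
  for (q in seq_along(lam)) {
    d <- lam[q] + S[, q]
    L <- L - 0.5 * outer(M[, q], Z[, q], "-")^2 / d - 0.5 * log(d / lam[q])
  }
  exp(L)
}

# Shared internals for psi2 and its adjoint: per-time factors over the
# flattened pair index k = (p, p').
.psi2_raw <- function(kernel, Z, beliefs) {
  lam <- kernel$lengthscales
  v <- kernel$variance
  M <- beliefs$mean
  S <- beliefs$var
  Tn <- nrow(M)
  P <- nrow(Z)
  Q <- length(lam)
  dzsq <- vector("list", Q)   # (z_p - z_p')^2, flattened length P^2
  zbar <- vector("list", Q)   # (z_p + z_p')/2
  cst <- 2 * log(v)
  dz <- 0
  for (q in seq_len(Q)) {
    dzsq[[q]] <- c(outer(Z[, q], Z[, q], "-"))^2
    zbar[[q]] <- c(outer(Z[, q], Z[, q], "+")) / 2
    dz <- dz + dzsq[[q]] / (4 * lam[q])
  }
  logW <- matrix(rep(cst - dz, each = Tn), Tn, P * P)
  for (q in seq_len(Q)) {
    d2 <- lam[q] + 2 * S[, q]
    logW <- logW - outer(M[, q], zbar[[q]], "-")^2 / d2 - 0.5 * log(d2 / lam[q])
  }
  list(W = exp(logW), dzsq = dzsq, zbar = zbar, Tn = Tn, P = P, Q = Q)
}

#' @rdname psi-statistics
#' @param by_time if \code{TRUE}, return the \code{T x P x P} array of
#'   per-time-step expectations instead of their sum over time.
#' @export
psi2 <- function(kernel, inducing, beliefs, by_time = FALSE) {
  .check_beliefs(kernel, beliefs)
  Z <- as.matrix(inducing)
  if (ncol(Z) != length(kernel$lengthscales)) {
    stop("inducing dimension does not match the number of kernel lengthscales")
  }
  raw <- .psi2_raw(kernel, Z, beliefs)
  if (by_time) {
    array(raw$W, dim = c(raw$Tn, raw$P, raw$P))
  } else {
    matrix(colSums(raw$W), raw$P, raw$P)
  }
}

# ---------------------------------------------------------------------------
# Vector-Jacobian products (adjoints).  Each takes the upstream gradient of
# some scalar loss with respect to the statistic and returns its gradients
# with respect to kernel parameters, belief moments and inducing locations.
# These power the analytic ELBO gradient; finite differences check them in
# the test suite.

.psi1_vjp <- function(kernel, Z, beliefs, G) {
  lam <- kernel$lengthscales
  M <- beliefs$mean
  S <- beliefs$var
  P1 <- psi1(kernel, Z, beliefs)
  WG <- P1 * G
  Q <- length(lam)
  d_mean <- matrix(0, nrow(M), Q)
  d_var <- matrix(0, nrow(M), Q)
  d_lam <- numeric(Q)
  d_Z <- matrix(0, nrow(Z), Q)
  rsWG <- rowSums(WG)
  for (q in seq_len(Q)) {
    d <- lam[q] + S[, q]
    Dq <- outer(-M[, q], Z[, q], "+") / d          # (z - mu)/d, T x P
    d_mean[, q] <- rowSums(WG * Dq)
    d_var[, q] <- 0.5 * rowSums(WG * Dq^2) - 0.5 * rsWG / d
    d_lam[q] <- 0.5 * sum(WG * Dq^2) + 0.5 * sum(rsWG * S[, q] / (lam[q] * d))
    d_Z[, q] <- -colSums(WG * Dq)
  }
  list(mean = d_mean, var = d_var, lengthscales = d_lam, Z = d_Z,
       variance = sum(WG) / kernel$variance)
}

.psi2_vjp <- function(kernel, Z, beliefs, G) {
  lam <- kernel$lengthscales
  M <- beliefs$mean
  S <- beliefs$var
  raw <- .psi2_raw(kernel, Z, beliefs)
  Tn <- raw$Tn
  P <- raw$P
  Q <- raw$Q
  g <- c(G)
  WG <- raw$W * rep(g, each = Tn)
  rsWG <- rowSums(WG)
  csWG <- colSums(WG)
  U <- matrix(csWG, P, P)
  d_mean <- matrix(0, Tn, Q)
  d_var <- matrix(0, Tn, Q)
  d_lam <- numeric(Q)
  d_Z <- matrix(0, P, Q)
  for (q in seq_len(Q)) {
    d2 <- lam[q] + 2 * S[, q]
    Dq <- outer(M[, q], raw$zbar[[q]], "-") / d2   # (mu - zbar)/d2, T x P^2
    WGD <- WG * Dq
    d_mean[, q] <- -2 * rowSums(WGD)
    d_var[, q] <- 2 * rowSums(WGD * Dq) - rsWG / d2
    d_lam[q] <- sum(WGD * Dq) + 0.5 * sum(WG) / lam[q] -
      0.5 * sum(rsWG / d2) + sum(csWG * raw$dzsq[[q]]) / (4 * lam[q]^2)
    Vq <- matrix(colSums(WGD), P, P)
    d_Z[, q] <- ((U + t(U)) %*% Z[, q] - (rowSums(U) + colSums(U)) * Z[, q]) /
      (2 * lam[q]) + rowSums(Vq) + colSums(Vq)
  }
  list(mean = d_mean, var = d_var, lengthscales = d_lam, Z = d_Z,
       variance = 2 * sum(WG) / kernel$variance)
}

# Adjoint of the (jittered) inducing Gram matrix K = k(Z, Z) + jit*v*I,
# where `jitter_scale` is the jitter expressed as a fraction of the signal
# variance (so the jitter moves with v).
.gram_vjp <- function(kernel, Z, G, jitter_scale = 0) {
  lam <- kernel$lengthscales
  K0 <- gram(kernel, Z)
  WG <- K0 * G
  Q <- length(lam)
  d_lam <- numeric(Q)
  d_Z <- matrix(0, nrow(Z), Q)
  for (q in seq_len(Q)) {
    dzq <- outer(Z[, q], Z[, q], "-")
    d_lam[q] <- sum(WG * dzq^2) / (2 * lam[q]^2)
    d_Z[, q] <- ((WG + t(WG)) %*% Z[, q] -
                   (rowSums(WG) + colSums(WG)) * Z[, q]) / lam[q]
  }
  list(lengthscales = d_lam, Z = d_Z,
       variance = sum(WG) / kernel$variance + jitter_scale * sum(diag(G)))
}
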