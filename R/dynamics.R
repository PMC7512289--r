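# Product-of-experts coupled latent dynamics and its collapsed variational
# bound.
#
# Every part j receives Gaussian predictions of its next latent state from
# all parts i (including itself) through coupling functions f^{i,j} with GP
# priors, evaluated at part i's stacked past states.  The predictions are
# fused by a product of experts with coupling variances alpha^{i,j}: the
# combined prediction has precision-weighted mean and variance
# alpha_j = (sum_i 1/alpha^{i,j})^{-1}.
#
# The collapsed bound for part j is obtained by writing the expected log
# PoE likelihood as a quadratic form in the stacked inducing values of all
# couplings into j (the cross terms between couplings factor into products
# of psi1 rows because the latent posterior factorizes over parts), and
# integrating the free-form q(u) out against the block-diagonal GP prior:
#
#   L_dyn^j = 1/2 sum_q h_q' (Ktilde + alpha_j B)^{-1} h_q
#             - Q/2 [ log|Ktilde + alpha_j B| - log|Ktilde| ]
#             - Tm Q/2 log(2 pi alpha_j) - 1/(2 alpha_j) sum (mu^2 + s2)
#             - alpha_j Q/2 sum_i (psi0_i - tr(K_i^{-1} Psi2_i)) / alpha_i^2
#
# with B_ii = Psi2_i/alpha_i^2, B_ii' = Psi1_i' Psi1_i' /(alpha_i alpha_i')
# and h_q = stack_i( Psi1_i' mu_q / alpha_i ).  The total dynamics bound
# adds the unit-Gaussian initial-state cross-entropy and the entropy of the
# latent posterior, which is booked here exactly once.

#' Coupling GP between an ordered pair of parts
#'
#' One directed coupling (source -> target): the GP-distributed function
#' that predicts the target part's next latent state from the source
#' part's stacked past states, sparsified by dynamics inducing points.
#'
#' @param source,target part indices (source predicts target).
#' @param kernel an \code{\link{ard_se_kernel}} over the source part's
#'   stacked past states (dimension \code{order * Q_source}).
#' @param inducing matrix \code{P x (order * Q_source)} of dynamics
#'   inducing point locations.
#' @param alpha positive coupling variance; small values mean strong
#'   influence of the source on the target.
#' @param posterior optional list with \code{mean} (\code{P x Q_target})
#'   holding the posterior inducing values, filled in after training.
#' @return object of class \code{"coupling_gp"}.
#' @export
coupling_gp <- function(source, target, kernel, inducing, alpha,
                        posterior = NULL) {
  if (alpha <= 0 || !is.finite(alpha)) stop("alpha must be positive and finite")
  inducing <- as.matrix(inducing)
  if (ncol(inducing) != length(kernel$lengthscales)) {
    stop("inducing dimension does not match the coupling kernel")
  }
  structure(list(source = source, target = target, kernel = kernel,
                 inducing = inducing, alpha = alpha, posterior = posterior),
            class = "coupling_gp")
}

#' Product-of-experts fusion of Gaussian predictions
#'
#' Multiplies Gaussian expert densities and renormalizes: the combined
#' variance is the inverse summed precision
#' \eqn{\alpha_j = (\sum_i 1/\alpha^{i,j})^{-1}} and the combined mean the
#' precision-weighted average of the expert means.
#'
#' @param means list (or matrix with one expert per row) of expert mean
#'   vectors.
#' @param variances numeric vector of positive per-expert variances.
#' @return list with \code{mean} and scalar \code{variance}.
#' @export
poe_combine <- function(means, variances) {
  if (is.matrix(means)) means <- asplit(means, 1)
  if (length(means) < 1L) stop("at least one expert is required")
  if (length(variances) != length(means)) {
    stop("one variance per expert is required")
  }
  if (any(variances <= 0) || !all(is.finite(variances))) {
    stop("expert variances must be positive and finite")
  }
  prec <- 1 / variances
  av <- 1 / sum(prec)
  m <- 0
  for (i in seq_along(means)) m <- m + prec[i] * as.numeric(means[[i]])
  list(mean = av * m, variance = av)
}

#' Marginalized product-of-experts dynamics kernel
#'
#' The kernel of the GP obtained when the individual per-part predictions
#' are marginalized exactly out of the product of experts: the
#' \eqn{\alpha}-weighted mean of the individual coupling kernels,
#' \eqn{k_f^j = \alpha_j^2 \sum_i k^{i,j}(\cdot,\cdot)/(\alpha^{i,j})^2}.
#' Kept as a cross-check oracle; training always uses the explicit sparse
#' couplings, which remain separable after learning.
#'
#' @param couplings list of \code{\link{coupling_gp}} objects sharing the
#'   same target part.
#' @param inputs a point matrix (shared by all couplings) or a list of
#'   point matrices, one per coupling in the source part's input space.
#' @param inputs2 optional second argument of the kernel, same layout.
#' @return combined Gram matrix.
#' @export
marginalized_kernel <- function(couplings, inputs, inputs2 = inputs) {
  tg <- vapply(couplings, function(cp) cp$target, numeric(1))
  if (length(unique(tg)) != 1L) stop("couplings must share one target part")
  if (!is.list(inputs)) inputs <- rep(list(inputs), length(couplings))
  if (!is.list(inputs2)) inputs2 <- rep(list(inputs2), length(couplings))
  alphas <- vapply(couplings, function(cp) cp$alpha, numeric(1))
  aj <- 1 / sum(1 / alphas)
  K <- 0
  for (i in seq_along(couplings)) {
    K <- K + gram(couplings[[i]]$kernel, inputs[[i]], inputs2[[i]]) / alphas[i]^2
  }
  aj^2 * K
}

#' Entropy of a factorized Gaussian latent posterior
#'
#' Shannon entropy of the diagonal-Gaussian posterior, summed over all
#' time steps, parts and latent dimensions:
#' \eqn{\sum \tfrac12 \log(2\pi e\, \sigma^2)}.
#'
#' @param posterior a \code{\link{belief_seq}} or a list of them (one per
#'   part).
#' @return scalar entropy in nats.
#' @export
entropy <- function(posterior) {
  if (inherits(posterior, "belief_seq")) posterior <- list(posterior)
  h <- 0
  for (p in posterior) {
    if (any(p$var <= 0)) stop("entropy requires strictly positive variances")
    h <- h + 0.5 * sum(log(2 * pi * exp(1) * p$var))
  }
  h
}

# Rows belonging to the first `order` states of each sequence.
.init_rows <- function(Tn, order, seq_id = NULL) {
  if (is.null(seq_id)) seq_id <- rep(1L, Tn)
  starts <- which(c(TRUE, seq_id[-1] != seq_id[-Tn]))
  c(outer(0:(order - 1), starts, "+"))
}

# Autoregressive index structure: for each target row t (beyond the first
# `order` rows of its sequence) the rows of the lagged states
# (t-order, ..., t-1).
.ar_index <- function(Tn, order, seq_id = NULL) {
  if (is.null(seq_id)) seq_id <- rep(1L, Tn)
  ok <- rep(TRUE, Tn)
  for (l in seq_len(order)) {
    lag_same <- c(rep(FALSE, l), seq_id[-seq_len(l)] == seq_id[seq_len(Tn - l)])
    ok <- ok & lag_same
  }
  target <- which(ok)
  if (length(target) == 0L) stop("sequences too short for the dynamics order")
  # column l holds the rows of x_{t-order+l-1}: oldest lag first
  lags <- sapply(seq_len(order), function(l) target - order + l - 1)
  list(target = target, lags = matrix(lags, ncol = order))
}

# Stacked belief over (x_{t-order}, ..., x_{t-1}) for one part.
.ar_beliefs <- function(posterior, lags) {
  m <- do.call(cbind, lapply(seq_len(ncol(lags)),
                             function(l) posterior$mean[lags[, l], , drop = FALSE]))
  v <- do.call(cbind, lapply(seq_len(ncol(lags)),
                             function(l) posterior$var[lags[, l], , drop = FALSE]))
  belief_seq(m, v)
}

#' Expected log-prior of the initial latent states
#'
#' Closed-form expectation under the latent posterior of the log density
#' of the first \code{order} states of every sequence under independent
#' unit Gaussians: \eqn{-\tfrac12\sum(\mu^2 + \sigma^2 + \log 2\pi)}.
#'
#' @inheritParams entropy
#' @param order dynamics order (number of initial states per sequence).
#' @param seq_id optional integer vector marking which sequence each time
#'   step belongs to (default: one sequence).
#' @return scalar.
#' @export
initial_state_term <- function(posterior, order = 2, seq_id = NULL) {
  if (inherits(posterior, "belief_seq")) posterior <- list(posterior)
  out <- 0
  for (p in posterior) {
    rows <- .init_rows(nrow(p$mean), order, seq_id)
    out <- out - 0.5 * sum(p$mean[rows, ]^2 + p$var[rows, ] + log(2 * pi))
  }
  out
}

# Per-coupling psi statistics on the source part's AR beliefs.
.coupling_stats <- function(cp, ar_bel, jitter) {
  K <- gram(cp$kernel, cp$inducing, jitter = jitter * cp$kernel$variance)
  cK <- .safe_chol(K)
  list(K = K, cK = cK, Kinv = chol2inv(cK),
       P1 = psi1(cp$kernel, cp$inducing, ar_bel),
       P2 = psi2(cp$kernel, cp$inducing, ar_bel),
       p0 = psi0(cp$kernel, ar_bel),
       alpha = cp$alpha, P = nrow(cp$inducing))
}

# Collapsed PoE bound for one target part; returns intermediates for the
# gradient and the joint optimal inducing posterior.
.dyn_part_core <- function(TM, TV, st) {
  Q <- ncol(TM)
  Tm <- nrow(TM)
  nb <- length(st)
  alphas <- vapply(st, `[[`, numeric(1), "alpha")
  aj <- 1 / sum(1 / alphas)
  Ps <- vapply(st, `[[`, numeric(1), "P")
  off <- cumsum(c(0, Ps))
  tot <- off[nb + 1]
  blk <- lapply(seq_len(nb), function(i) off[i] + seq_len(Ps[i]))
  B <- matrix(0, tot, tot)
  Ktil <- matrix(0, tot, tot)
  H <- matrix(0, tot, Q)
  for (i in seq_len(nb)) {
    Ktil[blk[[i]], blk[[i]]] <- st[[i]]$K
    B[blk[[i]], blk[[i]]] <- st[[i]]$P2 / alphas[i]^2
    H[blk[[i]], ] <- crossprod(st[[i]]$P1, TM) / alphas[i]
    if (i < nb) {
      for (i2 in (i + 1):nb) {
        Bij <- crossprod(st[[i]]$P1, st[[i2]]$P1) / (alphas[i] * alphas[i2])
        B[blk[[i]], blk[[i2]]] <- Bij
        B[blk[[i2]], blk[[i]]] <- t(Bij)
      }
    }
  }
  G <- Ktil + aj * B
  cG <- .safe_chol(G)
  Ginv <- chol2inv(cG)
  CH <- Ginv %*% H
  trs <- vapply(st, function(s) sum(s$Kinv * s$P2), numeric(1))
  p0s <- vapply(st, `[[`, numeric(1), "p0")
  logdetK <- sum(vapply(st, function(s) .logdet_chol(s$cK), numeric(1)))
  val <- 0.5 * sum(H * CH) -
    0.5 * Q * (.logdet_chol(cG) - logdetK) -
    0.5 * Tm * Q * log(2 * pi * aj) -
    0.5 * sum(TM^2 + TV) / aj -
    0.5 * aj * Q * sum((p0s - trs) / alphas^2)
  list(val = val, aj = aj, alphas = alphas, blk = blk, B = B, Ktil = Ktil,
       H = H, G = G, cG = cG, Ginv = Ginv, CH = CH, trs = trs, p0s = p0s,
       Q = Q, Tm = Tm, nb = nb)
}

# Joint optimal q(u) over all couplings into one part: block mean matrix
# (sum P_i) x Q and shared covariance.
.dyn_part_posterior <- function(core) {
  S <- core$Ktil %*% core$Ginv %*% core$Ktil
  list(mean = core$Ktil %*% core$CH, cov = (S + t(S)) / 2)
}

# Gradients of the collapsed part bound with respect to target moments,
# per-coupling statistics (chained through the psi adjoints by the caller)
# and coupling variances.
.dyn_part_grad <- function(TM, TV, st, core) {
  Q <- core$Q
  nb <- core$nb
  aj <- core$aj
  alphas <- core$alphas
  blk <- core$blk
  GG <- -0.5 * tcrossprod(core$CH) - 0.5 * Q * core$Ginv
  GB <- aj * GG
  d_TM <- -TM / aj
  d_TV <- matrix(-0.5 / aj, nrow(TV), ncol(TV))
  d_alpha <- numeric(nb)
  daj <- -0.5 * core$Tm * Q / aj + 0.5 * sum(TM^2 + TV) / aj^2 -
    0.5 * Q * sum((core$p0s - core$trs) / alphas^2) + sum(GG * core$B)
  out <- vector("list", nb)
  for (i in seq_len(nb)) {
    bi <- blk[[i]]
    CHi <- core$CH[bi, , drop = FALSE]
    Hi <- core$H[bi, , drop = FALSE]
    d_K <- GG[bi, bi] + 0.5 * Q * st[[i]]$Kinv -
      (0.5 * aj * Q / alphas[i]^2) *
        (st[[i]]$Kinv %*% st[[i]]$P2 %*% st[[i]]$Kinv)
    d_P2 <- GB[bi, bi] / alphas[i]^2 + (0.5 * aj * Q / alphas[i]^2) * st[[i]]$Kinv
    d_P1 <- TM %*% t(CHi) / alphas[i]
    da <- -(2 / alphas[i]) * sum(GB[bi, bi] * core$B[bi, bi]) -
      sum(CHi * Hi) / alphas[i] +
      (aj * Q / alphas[i]^3) * (core$p0s[i] - core$trs[i])
    for (i2 in seq_len(nb)[-i]) {
      bi2 <- blk[[i2]]
      d_P1 <- d_P1 + st[[i2]]$P1 %*%
        (t(GB[bi, bi2]) + GB[bi2, bi]) / (alphas[i] * alphas[i2])
      da <- da - sum(GB[bi, bi2] * core$B[bi, bi2]) / alphas[i] -
        sum(GB[bi2, bi] * core$B[bi2, bi]) / alphas[i]
    }
    d_TM <- d_TM + st[[i]]$P1 %*% CHi / alphas[i]
    d_alpha[i] <- da
    out[[i]] <- list(d_K = d_K, d_P1 = d_P1, d_P2 = d_P2,
                     d_p0 = -0.5 * aj * Q / alphas[i]^2)
  }
  d_alpha <- d_alpha + daj * aj^2 / alphas^2
  list(couplings = out, d_TM = d_TM, d_TV = d_TV, d_alpha = d_alpha)
}

#' Collapsed bound of the coupled latent dynamics
#'
#' The dynamics contribution to the model evidence lower bound: the
#' per-time expected log product-of-experts likelihood of every part's
#' latent state given the coupling predictions, with the coupling-function
#' values integrated against their sparse GP conditionals and the optimal
#' Gaussian posterior over inducing values collapsed in closed form; plus
#' the expected log-prior of the initial states under unit Gaussians and
#' the entropy of the latent posterior (booked here exactly once).
#'
#' @param posteriors list of \code{\link{belief_seq}} latent posteriors,
#'   one per part, all with the same number of rows.
#' @param couplings nested list: \code{couplings[[i]][[j]]} is the
#'   \code{\link{coupling_gp}} from part \code{i} to part \code{j}.
#' @param order autoregressive order of the dynamics (default 2).
#' @param seq_id optional integer vector marking sequence membership of
#'   each time step.
#' @param jitter Gram jitter fraction.
#' @param components if \code{TRUE}, also return the per-part bound terms,
#'   the initial-state term and the entropy.
#' @return scalar bound, or a list when \code{components = TRUE}.
#' @export
dynamics_bound <- function(posteriors, couplings, order = 2, seq_id = NULL,
                           jitter = .DEFAULT_JITTER, components = FALSE) {
  M <- length(posteriors)
  Tn <- nrow(posteriors[[1]]$mean)
  if (Tn < order + 1) stop("need more time steps than the dynamics order")
  idx <- .ar_index(Tn, order, seq_id)
  arb <- lapply(posteriors, .ar_beliefs, lags = idx$lags)
  per_part <- numeric(M)
  for (j in seq_len(M)) {
    st <- lapply(seq_len(M), function(i) {
      .coupling_stats(couplings[[i]][[j]], arb[[i]], jitter)
    })
    TM <- posteriors[[j]]$mean[idx$target, , drop = FALSE]
    TV <- posteriors[[j]]$var[idx$target, , drop = FALSE]
    per_part[j] <- .dyn_part_core(TM, TV, st)$val
  }
  ini <- initial_state_term(posteriors, order, seq_id)
  ent <- entropy(posteriors)
  if (components) {
    list(total = sum(per_part) + ini + ent, per_part = per_part,
         initial = ini, entropy = ent)
  } else {
    sum(per_part) + ini + ent
  }
}

# Expected log PoE likelihood (the first summand of the dynamics bound)
# for an explicit joint Gaussian q(u) with block mean `q_mean` and full
# covariance `q_cov` over the stacked inducing values of all couplings
# into one part.  Exposed for Monte-Carlo validation of the collapsed
# bound; O(T P^2) per time step.
.dyn_expected_loglik <- function(TM, TV, couplings_j, ar_beliefs, q_mean,
                                 q_cov, jitter = .DEFAULT_JITTER) {
  nb <- length(couplings_j)
  Q <- ncol(TM)
  Tm <- nrow(TM)
  st <- lapply(seq_len(nb), function(i) {
    .coupling_stats(couplings_j[[i]], ar_beliefs[[i]], jitter)
  })
  alphas <- vapply(st, `[[`, numeric(1), "alpha")
  aj <- 1 / sum(1 / alphas)
  Ps <- vapply(st, `[[`, numeric(1), "P")
  off <- cumsum(c(0, Ps))
  blk <- lapply(seq_len(nb), function(i) off[i] + seq_len(Ps[i]))
  P2t <- lapply(seq_len(nb), function(i) {
    psi2(couplings_j[[i]]$kernel, couplings_j[[i]]$inducing,
         ar_beliefs[[i]], by_time = TRUE)
  })
  total <- -0.5 * Tm * Q * log(2 * pi * aj)
  for (t in seq_len(Tm)) {
    quad <- sum(TM[t, ]^2 + TV[t, ])
    for (i in seq_len(nb)) {
      mi <- q_mean[blk[[i]], , drop = FALSE]
      phi <- st[[i]]$Kinv %*% st[[i]]$P1[t, ]
      quad <- quad - 2 * aj * sum(TM[t, ] * crossprod(mi, phi)) / alphas[i]
      # same-coupling second moment: tr(Kinv (m m' + S_ii) Kinv Psi2_t) + Q b_t
      Sii <- q_cov[blk[[i]], blk[[i]]]
      Mom <- tcrossprod(mi) + Q * Sii
      KiP2Ki <- st[[i]]$Kinv %*% P2t[[i]][t, , ] %*% st[[i]]$Kinv
      bt <- st[[i]]$p0 / Tm - sum(st[[i]]$Kinv * P2t[[i]][t, , ])
      quad <- quad + aj^2 * (sum(Mom * KiP2Ki) + Q * bt) / alphas[i]^2
      for (i2 in seq_len(nb)[-i]) {
        mi2 <- q_mean[blk[[i2]], , drop = FALSE]
        phi2 <- st[[i2]]$Kinv %*% st[[i2]]$P1[t, ]
        Cc <- q_cov[blk[[i]], blk[[i2]], drop = FALSE]
        cross <- sum((crossprod(mi, phi)) * (crossprod(mi2, phi2))) +
          Q * sum(phi * (Cc %*% phi2))
        quad <- quad + aj^2 * cross / (alphas[i] * alphas[i2])
      }
    }
    total <- total - 0.5 * quad / aj
  }
  total
}

# KL divergence between the joint Gaussian q(u) and the block-diagonal GP
# prior over stacked inducing values, with the covariance shared across the
# Q output dimensions.
.dyn_joint_kl <- function(q_mean, q_cov, st) {
  Ps <- vapply(st, `[[`, numeric(1), "P")
  off <- cumsum(c(0, Ps))
  tot <- off[length(st) + 1]
  Kinv <- matrix(0, tot, tot)
  logdetK <- 0
  for (i in seq_along(st)) {
    bi <- off[i] + seq_len(Ps[i])
    Kinv[bi, bi] <- st[[i]]$Kinv
    logdetK <- logdetK + .logdet_chol(st[[i]]$cK)
  }
  Q <- ncol(q_mean)
  cS <- .safe_chol(q_cov)
  0.5 * Q * (sum(Kinv * q_cov) - tot + logdetK - .logdet_chol(cS)) +
    0.5 * sum(q_mean * (Kinv %*% q_mean))
}
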