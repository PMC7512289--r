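# Trajectory generation and DTW-warped mean-squared-error scoring.

#' Generate a mean trajectory by iterating the learned dynamics
#'
#' Deterministically iterates the model: at every step each coupling's
#' sparse predictive mean is evaluated at the source part's stacked
#' previous states, the per-part predictions are fused by
#' \code{\link{poe_combine}}, and the combined means advance the latent
#' state; latent means are then mapped through the kinematics predictive
#' mean into observed space.  No sampling is involved, so identical
#' inputs give identical trajectories.
#'
#' @param model a trained \code{\link{vcgpdm}} with posteriors attached
#'   (see \code{\link{update_posteriors}}).
#' @param T_out number of frames to generate.
#' @param init_latents list (one entry per part) of \code{order x Q}
#'   matrices of initial latent states.  Alternatively \code{NULL} to use
#'   the first \code{order} rows of the model's own latent posterior.
#' @param init_frames instead of latent states, an \code{order x D}
#'   matrix of observed frames (e.g. the first frames of a held-out
#'   trial); each part's initial latents are found by least-squares
#'   inversion of its kinematics mean map.
#' @return list with \code{latents} (per-part \code{T_out x Q} matrices)
#'   and \code{observed} (\code{T_out x D} matrix in the model's column
#'   order, centers restored).
#' @export
rollout <- function(model, T_out, init_latents = NULL, init_frames = NULL) {
  M <- model$M
  order <- model$order
  for (i in seq_len(M)) {
    if (is.null(model$parts[[i]]$kin_posterior)) {
      stop("model has no kinematics posterior; run update_posteriors or fit first")
    }
    for (j in seq_len(M)) {
      if (is.null(model$couplings[[i]][[j]]$posterior)) {
        stop("model has no dynamics posterior; run update_posteriors or fit first")
      }
    }
  }
  if (T_out < order) stop("T_out must be at least the dynamics order")
  if (is.null(init_latents)) {
    if (!is.null(init_frames)) {
      init_frames <- as.matrix(init_frames)
      if (nrow(init_frames) != order) {
        stop("init_frames must have `order` rows")
      }
      init_latents <- lapply(seq_len(M), function(i) {
        .invert_kinematics(model, i,
                           init_frames[, model$parts[[i]]$cols, drop = FALSE])
      })
    } else {
      .check_initialized(model)
      init_latents <- lapply(model$parts, function(p) {
        p$latent$mean[seq_len(order), , drop = FALSE]
      })
    }
  }
  lat <- lapply(seq_len(M), function(i) {
    X <- matrix(NA_real_, T_out, model$parts[[i]]$Q)
    X[seq_len(order), ] <- as.matrix(init_latents[[i]])
    X
  })
  alphas <- matrix(sapply(seq_len(M), function(j) {
    vapply(seq_len(M), function(i) model$couplings[[i]][[j]]$alpha, numeric(1))
  }), M, M)  # rows = source i, cols = target j
  if (T_out > order) {
    for (t in (order + 1):T_out) {
      newx <- vector("list", M)
      for (j in seq_len(M)) {
        means <- lapply(seq_len(M), function(i) {
          cp <- model$couplings[[i]][[j]]
          xin <- c(t(lat[[i]][(t - order):(t - 1), , drop = FALSE]))
          xin <- matrix(xin, nrow = 1)
          sparse_predict(xin, cp$kernel, cp$inducing, cp$posterior,
                         jitter = model$jitter)$mean[1, ]
        })
        newx[[j]] <- poe_combine(means, alphas[, j])$mean
      }
      for (j in seq_len(M)) lat[[j]][t, ] <- newx[[j]]
      if (!all(is.finite(unlist(newx)))) {
        stop("non-finite latent state at rollout step ", t)
      }
    }
  }
  D <- length(model$column_map)
  obs <- matrix(NA_real_, T_out, D)
  for (i in seq_len(M)) {
    p <- model$parts[[i]]
    pred <- sparse_predict(lat[[i]], p$kin_kernel, p$kin_Z, p$kin_posterior,
                           jitter = model$jitter)
    obs[, p$cols] <- sweep(pred$mean, 2, p$center, "+")
  }
  list(latents = lat, observed = obs)
}

# Least-squares inversion of one part's kinematics mean map: find latent
# points whose predicted observations match the given (uncentered)
# frames.  Frames are solved in order, warm-starting each from the
# previous solution, so an inverted trajectory stays continuous.
.invert_kinematics <- function(model, i, frames) {
  p <- model$parts[[i]]
  Yc <- sweep(as.matrix(frames), 2, p$center)
  # candidate starts: inducing points (always available) plus training
  # latent means when present
  cand <- p$kin_Z
  if (!is.null(p$latent)) cand <- rbind(cand, p$latent$mean)
  cand_pred <- sparse_predict(cand, p$kin_kernel, p$kin_Z, p$kin_posterior,
                              jitter = model$jitter)$mean
  out <- matrix(0, nrow(Yc), p$Q)
  prev <- NULL
  for (r in seq_len(nrow(Yc))) {
    y <- Yc[r, ]
    x0 <- cand[which.min(colSums((t(cand_pred) - y)^2)), ]
    obj <- function(x) {
      m <- sparse_predict(matrix(x, 1), p$kin_kernel, p$kin_Z,
                          p$kin_posterior, jitter = model$jitter)$mean[1, ]
      sum((m - y)^2)
    }
    fit0 <- stats::optim(x0, obj, method = "BFGS",
                         control = list(maxit = 50, reltol = 1e-10))
    best <- fit0
    if (!is.null(prev)) {
      fit1 <- stats::optim(prev, obj, method = "BFGS",
                           control = list(maxit = 50, reltol = 1e-10))
      if (fit1$value < best$value) best <- fit1
    }
    out[r, ] <- best$par
    prev <- best$par
  }
  out
}

#' Dynamic-time-warping mean squared error
#'
#' Aligns two multivariate sequences with classic DTW (symmetric step
#' pattern: diagonal, horizontal and vertical steps with unit weights; no
#' window constraint) under squared-Euclidean local cost, and returns the
#' mean local cost along the optimal path.  Among paths of equal total
#' cost the shortest is used, which makes the result deterministic.
#'
#' @param generated,reference numeric matrices with equal column counts
#'   (frames in rows).
#' @return scalar mean squared error after warping.
#' @export
dtw_mse <- function(generated, reference) {
  al <- dtw_align(generated, reference)
  al$mse
}

#' @rdname dtw_mse
#' @return \code{dtw_align}: list with total path \code{cost}, path
#'   \code{length} (number of cells) and \code{mse = cost / length}.
#' @export
dtw_align <- function(generated, reference) {
  A <- as.matrix(generated)
  B <- as.matrix(reference)
  if (ncol(A) != ncol(B)) stop("sequences must have equal column counts")
  n <- nrow(A)
  m <- nrow(B)
  if (n == 0L || m == 0L) stop("empty sequence")
  # local squared-Euclidean cost
  d <- outer(rowSums(A^2), rep(1, m)) + outer(rep(1, n), rowSums(B^2)) -
    2 * A %*% t(B)
  d[d < 0] <- 0
  # lexicographic DP over (accumulated cost, path length)
  INF <- Inf
  Dc <- matrix(INF, n + 1, m + 1)
  Ln <- matrix(INF, n + 1, m + 1)
  Dc[1, 1] <- 0
  Ln[1, 1] <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      c3 <- c(Dc[i, j], Dc[i, j + 1], Dc[i + 1, j])
      l3 <- c(Ln[i, j], Ln[i, j + 1], Ln[i + 1, j])
      best <- which(c3 == min(c3))
      pick <- best[which.min(l3[best])]
      Dc[i + 1, j + 1] <- c3[pick] + d[i, j]
      Ln[i + 1, j + 1] <- l3[pick] + 1
    }
  }
  cost <- Dc[n + 1, m + 1]
  len <- Ln[n + 1, m + 1]
  list(cost = cost, length = len, mse = cost / len)
}

#' Leave-one-trial-out cross-validated DTW-MSE
#'
#' For each fold, trains a fresh model on the remaining trials, generates
#' a trajectory of the held-out trial's length starting from its first
#' \code{order} frames, and scores the generation against the complete
#' held-out trial with \code{\link{dtw_mse}}.
#'
#' @param data a \code{\link{trajectory_set}} with at least two
#'   sequences.
#' @param latent_dim,n_dyn_ips,n_kin_ips,order model structure passed to
#'   \code{\link{vcgpdm}}.
#' @param config a \code{\link{training_config}}.
#' @param k number of folds (default: number of trials, i.e.
#'   leave-one-out).  Trials are assigned to folds in order.
#' @return list with \code{folds} (data frame: fold, held-out trial,
#'   DTW-MSE), \code{mean} and \code{se} (standard error of the mean).
#' @export
cross_validate <- function(data, latent_dim = 3, n_dyn_ips = 8,
                           n_kin_ips = 10, order = 2,
                           config = training_config(), k = NULL) {
  ntr <- length(data$sequences)
  if (ntr < 2) stop("cross-validation requires at least two trials")
  if (is.null(k)) k <- ntr
  k <- min(k, ntr)
  fold_of <- rep(seq_len(k), length.out = ntr)
  rows <- list()
  for (f in seq_len(k)) {
    held <- which(fold_of == f)
    train <- trajectory_set(data$sequences[-held], data$column_map)
    fit <- fit_vcgpdm(vcgpdm(data$column_map, latent_dim, n_dyn_ips,
                             n_kin_ips, order),
                      train, config)
    for (h in held) {
      ref <- data$sequences[[h]]
      gen <- rollout(fit$model, nrow(ref),
                     init_frames = ref[seq_len(order), , drop = FALSE])
      rows[[length(rows) + 1L]] <-
        data.frame(fold = f, trial = h,
                   dtw_mse = dtw_mse(gen$observed, ref))
    }
  }
  folds <- do.call(rbind, rows)
  list(folds = folds, mean = mean(folds$dtw_mse),
       se = stats::sd(folds$dtw_mse) / sqrt(nrow(folds)))
}
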