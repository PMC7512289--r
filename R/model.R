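# The full coupled model: M parts, M^2 couplings, one ELBO.
#
# Each part owns a latent posterior, a kinematics GP (latent -> observed,
# sparsified by inducing points r) with isotropic noise beta, and is the
# target of M coupling GPs.  The ELBO decomposes as
#   L = sum_i L_kin^i + L_dyn
# where L_kin^i is the collapsed GP-regression bound of part i's observed
# columns given its latent beliefs, and L_dyn the collapsed coupled
# dynamics bound.  The latent-posterior entropy appears exactly once,
# inside L_dyn.

#' Construct a vCGPDM skeleton
#'
#' Builds an untrained coupled model for a given column-to-part
#' assignment.  Kernel parameters are placeholders until
#' \code{\link{init_vcgpdm}} (or \code{\link{fit_vcgpdm}}) sees data.
#'
#' @param column_map integer vector (or specification string) assigning
#'   each observed column to a part.
#' @param latent_dim latent dimensionality per part (recycled).
#' @param n_dyn_ips number of dynamics inducing points per coupling.
#' @param n_kin_ips number of kinematics inducing points per part.
#' @param order autoregressive order of the dynamics (default 2).
#' @param jitter Gram-matrix jitter as a fraction of the signal variance.
#' @return object of class \code{"vcgpdm"}.
#' @export
vcgpdm <- function(column_map, latent_dim = 3, n_dyn_ips = 10,
                   n_kin_ips = 10, order = 2, jitter = .DEFAULT_JITTER) {
  if (is.character(column_map)) stop("pass column_map through trajectory_set")
  column_map <- as.integer(column_map)
  M <- length(unique(column_map))
  if (!identical(sort(unique(column_map)), seq_len(M))) {
    stop("column_map parts must be consecutive integers starting at 1")
  }
  if (n_dyn_ips < 1 || n_kin_ips < 1) stop("inducing point counts must be >= 1")
  if (order < 1) stop("order must be >= 1")
  latent_dim <- rep(as.integer(latent_dim), length.out = M)
  parts <- lapply(seq_len(M), function(i) {
    cols <- which(column_map == i)
    Q <- latent_dim[i]
    list(cols = cols, D = length(cols), Q = Q,
         kin_kernel = ard_se_kernel(rep(1, Q)),
         kin_Z = matrix(0, n_kin_ips, Q),
         beta = 0.01, latent = NULL, kin_posterior = NULL,
         center = rep(0, length(cols)))
  })
  couplings <- lapply(seq_len(M), function(i) {
    lapply(seq_len(M), function(j) {
      Qi <- latent_dim[i]
      coupling_gp(i, j, ard_se_kernel(rep(1, order * Qi)),
                  matrix(0, n_dyn_ips, order * Qi), alpha = 1)
    })
  })
  structure(list(order = order, column_map = column_map, M = M,
                 parts = parts, couplings = couplings, seq_id = NULL,
                 jitter = jitter,
                 fixed = list(parts = rep(FALSE, M),
                              couplings = matrix(FALSE, M, M))),
            class = "vcgpdm")
}

#' @export
print.vcgpdm <- function(x, ...) {
  cat(sprintf("vCGPDM: %d part(s), order %d\n", x$M, x$order))
  for (i in seq_len(x$M)) {
    p <- x$parts[[i]]
    cat(sprintf("  part %d: D=%d Q=%d kin IPs=%d beta=%.3g%s\n", i, p$D, p$Q,
                nrow(p$kin_Z), p$beta,
                if (x$fixed$parts[i]) " [fixed]" else ""))
  }
  al <- sapply(seq_len(x$M), function(j)
    sapply(seq_len(x$M), function(i) x$couplings[[i]][[j]]$alpha))
  cat("  coupling variances alpha[i,j] (rows = source):\n")
  print(signif(matrix(al, x$M, x$M), 3))
  invisible(x)
}

# Stacked, per-part centered data matrices aligned with the model.
.model_data <- function(model, data) {
  st <- .stack_sequences(data)
  if (ncol(st$Y) != length(model$column_map)) {
    stop("data column count does not match the model's column map")
  }
  Ys <- lapply(model$parts, function(p) {
    sweep(st$Y[, p$cols, drop = FALSE], 2, p$center)
  })
  list(Ys = Ys, seq_id = st$seq_id, Tn = nrow(st$Y))
}

.check_initialized <- function(model) {
  for (p in model$parts) {
    if (is.null(p$latent)) stop("model has no latent posterior; initialize first")
  }
}

#' Evidence lower bound of a vCGPDM
#'
#' Computes \eqn{L = \sum_i L_{kin}^i + L_{dyn}} for the model's current
#' parameters and latent posterior on the given data.
#'
#' @param model an initialized \code{\link{vcgpdm}}.
#' @param data a \code{\link{trajectory_set}} consistent with the model's
#'   column map and latent posterior length.
#' @param components if \code{TRUE}, return the per-part kinematics terms
#'   and the dynamics decomposition alongside the total.
#' @return scalar bound, or a list when \code{components = TRUE}.
#' @export
elbo <- function(model, data, components = FALSE) {
  .check_initialized(model)
  md <- .model_data(model, data)
  kin <- vapply(seq_len(model$M), function(i) {
    p <- model$parts[[i]]
    collapsed_bound(md$Ys[[i]], p$kin_kernel, p$kin_Z, p$latent, p$beta,
                    jitter = model$jitter)
  }, numeric(1))
  posteriors <- lapply(model$parts, `[[`, "latent")
  dyn <- dynamics_bound(posteriors, model$couplings, model$order,
                        seq_id = md$seq_id, jitter = model$jitter,
                        components = components)
  if (components) {
    list(total = sum(kin) + dyn$total, kinematics = kin, dynamics = dyn)
  } else {
    sum(kin) + dyn
  }
}

#' Dedicated single-part (vGPDM) evidence lower bound
#'
#' Independent computation path for the uncoupled special case: the
#' dynamics term is the collapsed GP-regression bound of the latent
#' transitions (targets are the posterior means, noise is the part's
#' self-coupling variance) corrected for the variance of the random
#' targets, plus initial-state and entropy terms.  With \code{M = 1} the
#' full coupled bound must agree with this path; the product-of-experts
#' machinery reduces to it analytically.
#'
#' @inheritParams elbo
#' @return scalar bound.
#' @export
vgpdm_elbo <- function(model, data) {
  if (model$M != 1L) stop("vgpdm_elbo applies to single-part models")
  .check_initialized(model)
  md <- .model_data(model, data)
  p <- model$parts[[1]]
  cp <- model$couplings[[1]][[1]]
  kin <- collapsed_bound(md$Ys[[1]], p$kin_kernel, p$kin_Z, p$latent, p$beta,
                         jitter = model$jitter)
  idx <- .ar_index(nrow(p$latent$mean), model$order, md$seq_id)
  arb <- .ar_beliefs(p$latent, idx$lags)
  TM <- p$latent$mean[idx$target, , drop = FALSE]
  TV <- p$latent$var[idx$target, , drop = FALSE]
  dyn <- collapsed_bound(TM, cp$kernel, cp$inducing, arb, cp$alpha,
                         jitter = model$jitter) - sum(TV) / (2 * cp$alpha)
  kin + dyn + initial_state_term(p$latent, model$order, md$seq_id) +
    entropy(p$latent)
}

# ---------------------------------------------------------------------------
# Full ELBO gradient: analytic, assembled from the collapsed-bound and
# psi-statistic adjoints.  Returns the bound and a gradient structure
# mirroring the trainable parameters.

.elbo_grad <- function(model, data) {
  .check_initialized(model)
  md <- .model_data(model, data)
  M <- model$M
  order <- model$order
  jit <- model$jitter
  gparts <- lapply(model$parts, function(p) {
    list(mu = matrix(0, nrow(p$latent$mean), p$Q),
         var = matrix(0, nrow(p$latent$mean), p$Q),
         kin_lengthscales = numeric(p$Q), kin_variance = 0, beta = 0,
         kin_Z = matrix(0, nrow(p$kin_Z), p$Q))
  })
  gcoup <- lapply(seq_len(M), function(i) lapply(seq_len(M), function(j) {
    cp <- model$couplings[[i]][[j]]
    list(lengthscales = numeric(length(cp$kernel$lengthscales)),
         Z = matrix(0, nrow(cp$inducing), ncol(cp$inducing)), alpha = 0)
  }))
  total <- 0
  # kinematics terms
  for (i in seq_len(M)) {
    p <- model$parts[[i]]
    g <- .collapsed_bound_grad(md$Ys[[i]], p$kin_kernel, p$kin_Z, p$latent,
                               p$beta, jitter = jit)
    total <- total + g$bound
    gparts[[i]]$mu <- gparts[[i]]$mu + g$mean
    gparts[[i]]$var <- gparts[[i]]$var + g$var
    gparts[[i]]$kin_lengthscales <- g$lengthscales
    gparts[[i]]$kin_variance <- g$variance
    gparts[[i]]$beta <- g$noise
    gparts[[i]]$kin_Z <- g$Z
  }
  # dynamics terms
  Tn <- nrow(model$parts[[1]]$latent$mean)
  idx <- .ar_index(Tn, order, md$seq_id)
  posteriors <- lapply(model$parts, `[[`, "latent")
  arb <- lapply(posteriors, .ar_beliefs, lags = idx$lags)
  for (j in seq_len(M)) {
    st <- lapply(seq_len(M), function(i) {
      .coupling_stats(model$couplings[[i]][[j]], arb[[i]], jit)
    })
    TM <- posteriors[[j]]$mean[idx$target, , drop = FALSE]
    TV <- posteriors[[j]]$var[idx$target, , drop = FALSE]
    core <- .dyn_part_core(TM, TV, st)
    total <- total + core$val
    grd <- .dyn_part_grad(TM, TV, st, core)
    for (i in seq_len(M)) {
      cp <- model$couplings[[i]][[j]]
      v1 <- .psi1_vjp(cp$kernel, cp$inducing, arb[[i]], grd$couplings[[i]]$d_P1)
      v2 <- .psi2_vjp(cp$kernel, cp$inducing, arb[[i]], grd$couplings[[i]]$d_P2)
      vk <- .gram_vjp(cp$kernel, cp$inducing, grd$couplings[[i]]$d_K, jit)
      gcoup[[i]][[j]]$lengthscales <- v1$lengthscales + v2$lengthscales +
        vk$lengthscales
      gcoup[[i]][[j]]$Z <- v1$Z + v2$Z + vk$Z
      gcoup[[i]][[j]]$alpha <- grd$d_alpha[i]
      dm_ar <- v1$mean + v2$mean
      dv_ar <- v1$var + v2$var
      Qi <- model$parts[[i]]$Q
      for (l in seq_len(order)) {
        cols <- (l - 1) * Qi + seq_len(Qi)
        rows <- idx$lags[, l]
        # scatter-add AR input gradients back onto the latent grid
        for (q in seq_len(Qi)) {
          gparts[[i]]$mu[, q] <- gparts[[i]]$mu[, q] +
            .scatter_add(dm_ar[, cols[q]], rows, Tn)
          gparts[[i]]$var[, q] <- gparts[[i]]$var[, q] +
            .scatter_add(dv_ar[, cols[q]], rows, Tn)
        }
      }
    }
    gparts[[j]]$mu[idx$target, ] <- gparts[[j]]$mu[idx$target, ] + grd$d_TM
    gparts[[j]]$var[idx$target, ] <- gparts[[j]]$var[idx$target, ] + grd$d_TV
  }
  # initial-state prior and entropy
  for (i in seq_len(M)) {
    p <- model$parts[[i]]
    rows <- .init_rows(Tn, order, md$seq_id)
    total <- total - 0.5 * sum(p$latent$mean[rows, ]^2 + p$latent$var[rows, ] +
                                 log(2 * pi))
    gparts[[i]]$mu[rows, ] <- gparts[[i]]$mu[rows, ] - p$latent$mean[rows, ]
    gparts[[i]]$var[rows, ] <- gparts[[i]]$var[rows, ] - 0.5
    total <- total + 0.5 * sum(log(2 * pi * exp(1) * p$latent$var))
    gparts[[i]]$var <- gparts[[i]]$var + 0.5 / p$latent$var
  }
  list(value = total, parts = gparts, couplings = gcoup)
}

.scatter_add <- function(vals, rows, Tn) {
  out <- numeric(Tn)
  for (k in seq_along(rows)) out[rows[k]] <- out[rows[k]] + vals[k]
  out
}

# ---------------------------------------------------------------------------
# Parameter vector packing.  Positive parameters travel in log space.
# `groups` selects trainable blocks; components marked fixed in
# model$fixed keep their kernels, inducing points and noise frozen (their
# latent posterior remains trainable: it is a property of the data).

.param_slots <- function(model, groups) {
  slots <- list()
  add <- function(get, set, grad, log = FALSE) {
    slots[[length(slots) + 1L]] <<- list(get = get, set = set, grad = grad,
                                         log = log)
  }
  M <- model$M
  if ("latents" %in% groups) {
    for (i in seq_len(M)) {
      local({
        ii <- i
        add(function(m) c(m$parts[[ii]]$latent$mean),
            function(m, v) {
              m$parts[[ii]]$latent$mean[] <- v
              m
            },
            function(g) c(g$parts[[ii]]$mu))
        add(function(m) c(m$parts[[ii]]$latent$var),
            function(m, v) {
              m$parts[[ii]]$latent$var[] <- v
              m
            },
            function(g) c(g$parts[[ii]]$var), log = TRUE)
      })
    }
  }
  if ("hypers" %in% groups) {
    for (i in seq_len(M)) {
      if (model$fixed$parts[i]) next
      local({
        ii <- i
        add(function(m) m$parts[[ii]]$kin_kernel$lengthscales,
            function(m, v) {
              m$parts[[ii]]$kin_kernel$lengthscales <- v
              m
            },
            function(g) g$parts[[ii]]$kin_lengthscales, log = TRUE)
        add(function(m) m$parts[[ii]]$kin_kernel$variance,
            function(m, v) {
              m$parts[[ii]]$kin_kernel$variance <- v
              m
            },
            function(g) g$parts[[ii]]$kin_variance, log = TRUE)
        add(function(m) m$parts[[ii]]$beta,
            function(m, v) {
              m$parts[[ii]]$beta <- v
              m
            },
            function(g) g$parts[[ii]]$beta, log = TRUE)
      })
    }
    for (i in seq_len(M)) {
      for (j in seq_len(M)) {
        if (model$fixed$couplings[i, j]) next
        local({
          ii <- i
          jj <- j
          add(function(m) m$couplings[[ii]][[jj]]$kernel$lengthscales,
              function(m, v) {
                m$couplings[[ii]][[jj]]$kernel$lengthscales <- v
                m
              },
              function(g) g$couplings[[ii]][[jj]]$lengthscales, log = TRUE)
        })
      }
    }
  }
  if ("alphas" %in% groups) {
    for (i in seq_len(M)) {
      for (j in seq_len(M)) {
        local({
          ii <- i
          jj <- j
          add(function(m) m$couplings[[ii]][[jj]]$alpha,
              function(m, v) {
                m$couplings[[ii]][[jj]]$alpha <- v
                m
              },
              function(g) g$couplings[[ii]][[jj]]$alpha, log = TRUE)
        })
      }
    }
  }
  if ("inducing" %in% groups) {
    for (i in seq_len(M)) {
      if (!model$fixed$parts[i]) {
        local({
          ii <- i
          add(function(m) c(m$parts[[ii]]$kin_Z),
              function(m, v) {
                m$parts[[ii]]$kin_Z[] <- v
                m
              },
              function(g) c(g$parts[[ii]]$kin_Z))
        })
      }
      for (j in seq_len(M)) {
        if (model$fixed$couplings[i, j]) next
        local({
          ii <- i
          jj <- j
          add(function(m) c(m$couplings[[ii]][[jj]]$inducing),
              function(m, v) {
                m$couplings[[ii]][[jj]]$inducing[] <- v
                m
              },
              function(g) c(g$couplings[[ii]][[jj]]$Z))
        })
      }
    }
  }
  slots
}

.pack_params <- function(model, slots) {
  unlist(lapply(slots, function(s) {
    v <- s$get(model)
    if (s$log) log(v) else v
  }), use.names = FALSE)
}

.unpack_params <- function(model, vec, slots) {
  k <- 0L
  for (s in slots) {
    n <- length(s$get(model))
    v <- vec[k + seq_len(n)]
    if (s$log) v <- exp(v)
    model <- s$set(model, v)
    k <- k + n
  }
  model
}

.pack_grad <- function(model, grad, slots) {
  unlist(lapply(slots, function(s) {
    g <- s$grad(grad)
    if (s$log) g <- g * s$get(model)   # chain rule through log transform
    g
  }), use.names = FALSE)
}

# ---------------------------------------------------------------------------
# Posterior computation (after training): closed-form optimal q(v) for the
# kinematics of every part and joint optimal q(u) for the couplings into
# every part, stored on the model for trajectory generation.

#' Compute and store the optimal inducing-value posteriors
#'
#' Fills in the closed-form optimal Gaussian posteriors over kinematics
#' and dynamics inducing values for the model's current parameters, as
#' needed for trajectory generation.
#'
#' @inheritParams elbo
#' @return the model with posteriors attached.
#' @export
update_posteriors <- function(model, data) {
  .check_initialized(model)
  md <- .model_data(model, data)
  M <- model$M
  for (i in seq_len(M)) {
    p <- model$parts[[i]]
    model$parts[[i]]$kin_posterior <-
      optimal_inducing_posterior(md$Ys[[i]], p$kin_kernel, p$kin_Z, p$latent,
                                 p$beta, jitter = model$jitter)
  }
  Tn <- nrow(model$parts[[1]]$latent$mean)
  idx <- .ar_index(Tn, model$order, md$seq_id)
  posteriors <- lapply(model$parts, `[[`, "latent")
  arb <- lapply(posteriors, .ar_beliefs, lags = idx$lags)
  for (j in seq_len(M)) {
    st <- lapply(seq_len(M), function(i) {
      .coupling_stats(model$couplings[[i]][[j]], arb[[i]], model$jitter)
    })
    TM <- posteriors[[j]]$mean[idx$target, , drop = FALSE]
    TV <- posteriors[[j]]$var[idx$target, , drop = FALSE]
    core <- .dyn_part_core(TM, TV, st)
    qu <- .dyn_part_posterior(core)
    off <- 0L
    for (i in seq_len(M)) {
      P <- nrow(model$couplings[[i]][[j]]$inducing)
      model$couplings[[i]][[j]]$posterior <-
        list(mean = qu$mean[off + seq_len(P), , drop = FALSE])
      off <- off + P
    }
  }
  model
}

# ---------------------------------------------------------------------------
# Serialization: a versioned JSON archive holding inducing points/values,
# kernel and coupling parameters, noise variances, the order and column
# map.  Numbers are written with 17 significant digits, which round-trips
# IEEE doubles exactly.  The latent posterior (whose size grows with the
# training length) is included only on request.

.ARCHIVE_VERSION <- 1L

#' Save / load a vCGPDM archive
#'
#' \code{save_vcgpdm} writes a JSON archive of the model: per part the
#' kinematics kernel, inducing points and values, noise variance and
#' column centers; per coupling the kernel, inducing points and values and
#' the coupling variance; plus order and column map.  Without latents the
#' archive size is independent of the training length.  All numbers are
#' stored with 17 significant digits so \code{load_vcgpdm} reproduces the
#' model (and its ELBO on identical data) exactly.
#'
#' @param model a \code{\link{vcgpdm}}.
#' @param path file path of the archive.
#' @param latents include the latent posterior (needed to re-evaluate the
#'   ELBO after loading; default \code{FALSE}).
#' @return \code{save_vcgpdm}: the path, invisibly; \code{load_vcgpdm}:
#'   the reconstructed model.
#' @export
save_vcgpdm <- function(model, path, latents = FALSE) {
  ser_part <- function(p) {
    list(D = p$D, Q = p$Q, cols = p$cols,
         kin_lengthscales = p$kin_kernel$lengthscales,
         kin_variance = p$kin_kernel$variance,
         kin_Z = p$kin_Z, beta = p$beta, center = p$center,
         kin_values = if (!is.null(p$kin_posterior)) p$kin_posterior$mean)
  }
  ser_coup <- function(cp) {
    list(source = cp$source, target = cp$target,
         lengthscales = cp$kernel$lengthscales, alpha = cp$alpha,
         Z = cp$inducing,
         values = if (!is.null(cp$posterior)) cp$posterior$mean)
  }
  obj <- list(format = "vcgpdm-archive", version = .ARCHIVE_VERSION,
              order = model$order, column_map = model$column_map,
              jitter = model$jitter,
              fixed_parts = model$fixed$parts,
              fixed_couplings = model$fixed$couplings,
              parts = lapply(model$parts, ser_part),
              couplings = lapply(seq_len(model$M), function(i) {
                lapply(seq_len(model$M), function(j) {
                  ser_coup(model$couplings[[i]][[j]])
                })
              }))
  if (latents) {
    obj$latents <- lapply(model$parts, function(p) {
      list(mean = p$latent$mean, var = p$latent$var)
    })
    obj$seq_id <- model$seq_id
  }
  writeLines(jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE,
                              null = "null"), path)
  invisible(path)
}

#' @rdname save_vcgpdm
#' @export
load_vcgpdm <- function(path) {
  if (!file.exists(path)) stop("archive not found: ", path)
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                            simplifyMatrix = TRUE)
  if (!identical(obj$format, "vcgpdm-archive")) {
    stop("not a vCGPDM archive: ", path)
  }
  if (obj$version > .ARCHIVE_VERSION) {
    stop("archive version ", obj$version, " is newer than this package supports")
  }
  M <- length(obj$parts)
  model <- vcgpdm(column_map = obj$column_map,
                  latent_dim = vapply(obj$parts, `[[`, numeric(1), "Q"),
                  n_dyn_ips = nrow(as.matrix(obj$couplings[[1]][[1]]$Z)),
                  n_kin_ips = nrow(as.matrix(obj$parts[[1]]$kin_Z)),
                  order = obj$order, jitter = obj$jitter)
  for (i in seq_len(M)) {
    p <- obj$parts[[i]]
    model$parts[[i]]$kin_kernel <- ard_se_kernel(p$kin_lengthscales,
                                                 p$kin_variance)
    model$parts[[i]]$kin_Z <- as.matrix(p$kin_Z)
    model$parts[[i]]$beta <- p$beta
    model$parts[[i]]$center <- as.numeric(p$center)
    if (!is.null(p$kin_values)) {
      model$parts[[i]]$kin_posterior <- list(mean = as.matrix(p$kin_values))
    }
    for (j in seq_len(M)) {
      cp <- obj$couplings[[i]][[j]]
      model$couplings[[i]][[j]] <- coupling_gp(
        i, j, ard_se_kernel(cp$lengthscales), as.matrix(cp$Z), cp$alpha,
        posterior = if (!is.null(cp$values)) list(mean = as.matrix(cp$values)))
    }
  }
  model$fixed$parts <- as.logical(obj$fixed_parts)
  model$fixed$couplings <- matrix(as.logical(obj$fixed_couplings), M, M)
  if (!is.null(obj$latents)) {
    for (i in seq_len(M)) {
      model$parts[[i]]$latent <- belief_seq(as.matrix(obj$latents[[i]]$mean),
                                            as.matrix(obj$latents[[i]]$var))
    }
    model$seq_id <- if (!is.null(obj$seq_id)) as.integer(obj$seq_id)
  }
  model
}

# ---------------------------------------------------------------------------

#' Compose a model from previously trained components
#'
#' Builds a new coupled model that reuses trained parts (kinematics plus
#' latent structure) and couplings as frozen modules, so that a library of
#' movement primitives can be recombined.  Components listed in
#' \code{fixed_parts} / \code{fixed_couplings} keep their kernels, noise
#' and inducing points during subsequent fitting; the coupling variances
#' \eqn{\alpha^{i,j}} are (re)trained by default, mirroring modular reuse
#' where only the couplings between reused primitives are learned anew.
#'
#' @param parts list of part structures (from trained \code{vcgpdm}
#'   objects, e.g. \code{model$parts[[1]]}).
#' @param couplings nested list \code{couplings[[i]][[j]]} of
#'   \code{\link{coupling_gp}} objects for every ordered pair.
#' @param column_map column-to-part assignment of the composed model.
#' @param order dynamics order (must match the couplings' input spaces).
#' @param fixed_parts logical vector marking parts to freeze.
#' @param fixed_couplings logical matrix marking couplings to freeze.
#' @param keep_latents keep the parts' latent posteriors (valid only when
#'   the composed model will be used with the same data they were trained
#'   on); otherwise latents are reset and must be re-initialized.
#' @param jitter Gram jitter fraction.
#' @return a \code{\link{vcgpdm}}.
#' @export
vcgpdm_compose <- function(parts, couplings, column_map, order = 2,
                           fixed_parts = NULL, fixed_couplings = NULL,
                           keep_latents = TRUE, jitter = .DEFAULT_JITTER) {
  M <- length(parts)
  column_map <- as.integer(column_map)
  model <- vcgpdm(column_map,
                  latent_dim = vapply(parts, `[[`, numeric(1), "Q"),
                  n_dyn_ips = nrow(couplings[[1]][[1]]$inducing),
                  n_kin_ips = nrow(parts[[1]]$kin_Z),
                  order = order, jitter = jitter)
  for (i in seq_len(M)) {
    if (!identical(as.integer(parts[[i]]$cols),
                   as.integer(which(column_map == i)))) {
      # column indices may differ between source and composed model;
      # only the count must match
      if (length(parts[[i]]$cols) != sum(column_map == i)) {
        stop("part ", i, " column count does not match the column map")
      }
    }
    model$parts[[i]] <- parts[[i]]
    model$parts[[i]]$cols <- which(column_map == i)
    if (!keep_latents) model$parts[[i]]$latent <- NULL
    for (j in seq_len(M)) {
      cp <- couplings[[i]][[j]]
      if (ncol(cp$inducing) != order * parts[[i]]$Q) {
        stop("coupling (", i, ",", j, ") input dimension is incompatible")
      }
      model$couplings[[i]][[j]] <- coupling_gp(i, j, cp$kernel, cp$inducing,
                                               cp$alpha, cp$posterior)
    }
  }
  if (!is.null(fixed_parts)) model$fixed$parts <- fixed_parts
  if (!is.null(fixed_couplings)) model$fixed$couplings <- fixed_couplings
  model
}
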