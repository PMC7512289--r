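# Initialization and optimization.
#
# Latent trajectories start at the leading principal-component scores of
# each part's observed columns; inducing points are drawn from the initial
# latent trajectory, stratified over time.  Training maximizes the ELBO
# with L-BFGS-B, first jointly over all parameters and then in blocked
# cycles over three groups: latent moments, kernel/coupling parameters,
# and inducing points.

#' Training configuration
#'
#' @param max_joint_iters iteration cap of the initial joint optimization
#'   stage (default 500).
#' @param max_block_iters iteration cap per block within a cycle.
#' @param max_cycles maximum number of blocked cycles (default 4).
#' @param tol relative ELBO change between cycles below which training
#'   stops (default 1e-6).
#' @param blocks block schedule; a character vector over
#'   \code{"latents"}, \code{"hypers"} (kernel parameters, noise and
#'   coupling variances) and \code{"inducing"}.
#' @param seed integer seed used wherever initialization draws random
#'   numbers.
#' @return object of class \code{"training_config"}.
#' @export
training_config <- function(max_joint_iters = 500, max_block_iters = 100,
                            max_cycles = 4, tol = 1e-6,
                            blocks = c("latents", "hypers", "inducing"),
                            seed = 1) {
  known <- c("latents", "hypers", "inducing")
  if (!all(blocks %in% known)) stop("unknown block name")
  if (!setequal(blocks, known)) {
    stop("blocks must cover all trainable groups exactly once per cycle")
  }
  structure(list(max_joint_iters = max_joint_iters,
                 max_block_iters = max_block_iters,
                 max_cycles = max_cycles, tol = tol, blocks = blocks,
                 seed = as.integer(seed)),
            class = "training_config")
}

#' Read a training configuration from a key = value file
#'
#' Plain-text configuration: one \code{key = value} pair per line,
#' \code{#} comments allowed.  Unknown keys are an error.  The
#' \code{blocks} key takes a comma-separated list.
#'
#' @param path file path.
#' @return a \code{\link{training_config}}.
#' @export
read_training_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: '", ln, "'")
    key <- trimws(kv[1])
    val <- trimws(kv[2])
    args[[key]] <- if (key == "blocks") {
      trimws(strsplit(val, ",")[[1]])
    } else {
      as.numeric(val)
    }
  }
  do.call(training_config, args)
}

#' PCA initialization of the latent posterior
#'
#' Means are the first \code{Q} principal-component scores of the part's
#' observed columns (sequences concatenated, columns centered;
#' zero-variance columns are dropped from the PCA rather than failing);
#' variances start at a small constant.
#'
#' @param data a \code{\link{trajectory_set}}.
#' @param cols observed column indices of the part.
#' @param Q latent dimensionality.
#' @param init_var initial posterior variance (default 0.1).
#' @return a \code{\link{belief_seq}}; deterministic given the data.
#' @export
init_latent <- function(data, cols, Q, init_var = 0.1) {
  st <- .stack_sequences(data)
  Y <- st$Y[, cols, drop = FALSE]
  if (nrow(Y) < Q) stop("need at least Q time steps for PCA initialization")
  keep <- which(apply(Y, 2, stats::sd) > 0)
  if (length(keep) == 0L) {
    scores <- matrix(0, nrow(Y), Q)
  } else {
    pc <- stats::prcomp(Y[, keep, drop = FALSE], center = TRUE, scale. = FALSE)
    k <- min(Q, ncol(pc$x))
    scores <- matrix(0, nrow(Y), Q)
    scores[, seq_len(k)] <- pc$x[, seq_len(k)]
    # canonical sign: largest-magnitude loading of each component positive
    for (q in seq_len(k)) {
      ld <- pc$rotation[, q]
      if (ld[which.max(abs(ld))] < 0) scores[, q] <- -scores[, q]
    }
  }
  belief_seq(scores, init_var)
}

#' Select inducing points from a candidate trajectory
#'
#' Picks \code{P} rows of \code{points}, stratified over time: the row
#' range is split into \code{P} equal strata and one row is sampled
#' uniformly from each, reproducibly under \code{seed}.
#'
#' @param points candidate point matrix (e.g. initial latent means, or
#'   stacked autoregressive means for dynamics inducing points).
#' @param P number of inducing points.
#' @param seed integer seed.
#' @return \code{P x ncol(points)} matrix.
#' @export
init_inducing <- function(points, P, seed = 1) {
  points <- as.matrix(points)
  Tn <- nrow(points)
  if (P > Tn) {
    warning("more inducing points than candidate rows; sampling with replacement")
  }
  rows <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, globalenv())
    })
    set.seed(seed)
    bounds <- floor(seq(0, Tn, length.out = P + 1))
    vapply(seq_len(P), function(k) {
      lo <- bounds[k] + 1
      hi <- max(bounds[k + 1], lo)
      if (hi > lo) sample(lo:hi, 1) else lo
    }, numeric(1))
  })
  points[rows, , drop = FALSE]
}

# Median pairwise squared distance, the lengthscale heuristic.
.median_sqdist <- function(X, max_n = 500) {
  X <- as.matrix(X)
  if (nrow(X) > max_n) X <- X[round(seq(1, nrow(X), length.out = max_n)), , drop = FALSE]
  d <- as.numeric(stats::dist(X))^2
  m <- stats::median(d[d > 0])
  if (!is.finite(m) || m <= 0) 1 else m
}

#' Initialize a vCGPDM on data
#'
#' PCA latents, stratified inducing points, median-distance lengthscales,
#' unit coupling variances and noise at 1% of the data variance.
#'
#' @param model a \code{\link{vcgpdm}} skeleton.
#' @param data a \code{\link{trajectory_set}}.
#' @param seed integer seed for the inducing-point selection.
#' @return the initialized model.
#' @export
init_vcgpdm <- function(model, data, seed = 1) {
  st <- .stack_sequences(data)
  model$seq_id <- st$seq_id
  M <- model$M
  for (i in seq_len(M)) {
    p <- model$parts[[i]]
    if (model$fixed$parts[i] && !is.null(p$latent)) next
    if (model$fixed$parts[i] && !is.null(p$kin_posterior)) {
      # a frozen, trained part defines its own latent coordinates: start
      # from the least-squares inversion of its kinematics map rather
      # than from PCA scores, which live in an unrelated frame
      lat <- belief_seq(.invert_kinematics(model, i,
                                           st$Y[, p$cols, drop = FALSE]),
                        0.1)
    } else {
      lat <- init_latent(data, p$cols, p$Q)
    }
    model$parts[[i]]$latent <- lat
    if (!model$fixed$parts[i]) {
      model$parts[[i]]$center <- colMeans(st$Y[, p$cols, drop = FALSE])
      model$parts[[i]]$kin_Z <- init_inducing(lat$mean, nrow(p$kin_Z),
                                              seed = seed + i)
      model$parts[[i]]$kin_kernel <-
        ard_se_kernel(rep(.median_sqdist(lat$mean), p$Q), variance = 1)
      yv <- mean(apply(sweep(st$Y[, p$cols, drop = FALSE], 2,
                             model$parts[[i]]$center), 2, stats::var))
      model$parts[[i]]$beta <- max(0.01 * yv, 1e-8)
      # kinematics signal variance at the data variance scale
      model$parts[[i]]$kin_kernel$variance <- max(yv, 1e-8)
    }
  }
  idx <- .ar_index(nrow(st$Y), model$order, st$seq_id)
  for (i in seq_len(M)) {
    ar <- .ar_beliefs(model$parts[[i]]$latent, idx$lags)
    for (j in seq_len(M)) {
      if (model$fixed$couplings[i, j]) next
      cp <- model$couplings[[i]][[j]]
      Znew <- init_inducing(ar$mean, nrow(cp$inducing),
                            seed = seed + 100 + i * M + j)
      lam <- rep(.median_sqdist(ar$mean), ncol(ar$mean))
      model$couplings[[i]][[j]] <- coupling_gp(
        i, j, ard_se_kernel(lam), Znew, cp$alpha)
    }
  }
  model
}

#' Fit a vCGPDM by joint-then-blocked ELBO maximization
#'
#' Runs one joint L-BFGS-B optimization over all trainable parameters,
#' then cycles of blocked optimization over the configured groups until
#' the relative ELBO change between cycles drops below \code{tol} or the
#' cycle cap is reached.  The trace records the ELBO after every stage.
#' Components frozen via \code{model$fixed} (see
#' \code{\link{vcgpdm_compose}}) keep their parameters; coupling
#' variances are always trainable.
#'
#' @param model a \code{\link{vcgpdm}}; initialized automatically if it
#'   has no latent posterior yet.
#' @param data a \code{\link{trajectory_set}}.
#' @param config a \code{\link{training_config}}.
#' @param groups parameter groups to train; default all
#'   (\code{"latents"}, \code{"hypers"}, \code{"alphas"},
#'   \code{"inducing"}).  Restricting to \code{"alphas"} retrains only
#'   the coupling variances of a composed model.
#' @return list with elements \code{model} (trained, posteriors attached)
#'   and \code{trace} (data frame of stage, cycle, block, ELBO).
#' @export
fit_vcgpdm <- function(model, data, config = training_config(),
                       groups = c("latents", "hypers", "alphas", "inducing")) {
  if (any(vapply(model$parts, function(p) is.null(p$latent), logical(1)))) {
    model <- init_vcgpdm(model, data, seed = config$seed)
  }
  st <- .stack_sequences(data)
  model$seq_id <- st$seq_id
  trace <- data.frame(stage = character(), cycle = integer(),
                      block = character(), elbo = numeric())
  push <- function(stage, cycle, block, value) {
    trace[nrow(trace) + 1L, ] <<- list(stage, cycle, block, value)
  }
  run_stage <- function(model, stage_groups, maxit) {
    slots <- .param_slots(model, stage_groups)
    if (length(slots) == 0L) return(model)
    par0 <- .pack_params(model, slots)
    # box-constrain only the log-space (positivity) parameters
    lower <- unlist(lapply(slots, function(s) {
      rep(if (s$log) -30 else -Inf, length(s$get(model)))
    }))
    upper <- unlist(lapply(slots, function(s) {
      rep(if (s$log) 30 else Inf, length(s$get(model)))
    }))
    cache <- new.env(parent = emptyenv())
    cache$par <- NULL
    evalg <- function(par) {
      if (!identical(par, cache$par)) {
        m2 <- .unpack_params(model, par, slots)
        g <- tryCatch(.elbo_grad(m2, data), error = function(e) NULL)
        if (is.null(g) || !is.finite(g$value)) {
          cache$val <- -1e12
          cache$grad <- rep(0, length(par))
        } else {
          cache$val <- g$value
          cache$grad <- .pack_grad(m2, g, slots)
        }
        cache$par <- par
      }
      invisible(NULL)
    }
    fn <- function(par) {
      evalg(par)
      -cache$val
    }
    gr <- function(par) {
      evalg(par)
      -cache$grad
    }
    f0 <- fn(par0)
    res <- stats::optim(par0, fn, gr, method = "L-BFGS-B",
                        control = list(maxit = maxit),
                        lower = lower, upper = upper)
    if (!(res$convergence %in% c(0L, 1L))) {
      warning("optimizer reported: ", res$message,
              "; keeping best-so-far state")
    }
    # keep the better of start and end point
    if (res$value <= f0) model <- .unpack_params(model, res$par, slots)
    model
  }
  # map configured blocks onto slot groups ("hypers" includes alphas)
  expand_block <- function(b) {
    if (b == "hypers") c("hypers", "alphas") else b
  }
  sel <- function(g) intersect(g, groups)
  e0 <- elbo(model, data)
  push("init", 0L, "", e0)
  joint_groups <- sel(unlist(lapply(config$blocks, expand_block)))
  if (length(joint_groups) > 0 && config$max_joint_iters > 0) {
    model <- run_stage(model, joint_groups, config$max_joint_iters)
    push("joint", 0L, paste(joint_groups, collapse = "+"), elbo(model, data))
  }
  prev <- elbo(model, data)
  for (cyc in seq_len(config$max_cycles)) {
    for (b in config$blocks) {
      g <- sel(expand_block(b))
      if (length(g) == 0L) next
      model <- run_stage(model, g, config$max_block_iters)
      push("block", cyc, b, elbo(model, data))
    }
    cur <- elbo(model, data)
    if (abs(cur - prev) <= config$tol * abs(prev)) break
    prev <- cur
  }
  model <- update_posteriors(model, data)
  list(model = model, trace = trace)
}
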