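# Synthetic coupled-system data with known ground-truth coupling.
#
# Emulates the construction used to illustrate coupled latent learning:
# two first-order latent systems in R^2 driven by functions drawn from GP
# priors, with asymmetric coupling
#   x^1_t = g1(x^1_{t-1})
#   x^2_t = w12 * g1(x^1_{t-1}) + w22 * g2(x^2_{t-1})
# so that system 1 is autonomous while system 2 is weakly driven by
# system 1.  Each part is then observed through further GP-drawn
# kinematics functions of its latent trajectory plus isotropic noise.

#' Specification of a synthetic coupled dataset
#'
#' @param T number of time steps per trajectory (default 300).
#' @param Q latent dimensionality per part (default 2).
#' @param w_cross weight of system 1's transition function in system 2's
#'   update (default 0.1).
#' @param w_self weight of system 2's own transition (default 0.9).
#' @param D_obs observed dimensions per part (default 10).
#' @param dyn_lengthscale squared lengthscale of the GP prior the
#'   transition functions are drawn from.
#' @param obs_lengthscale squared lengthscale of the GP prior the
#'   kinematics functions are drawn from.
#' @param noise_var isotropic observation noise variance (default 1e-4).
#' @param seed integer seed; the generator is a pure function of the spec.
#' @param variant nonnegative integer selecting a movement variant:
#'   variants share system 1 (same transition function, same initial
#'   state, hence bitwise-identical part-1 data) but re-draw system 2's
#'   transition function and initial state.  Used to study modular
#'   recombination of a shared part across movements.
#' @return object of class \code{"synthetic_spec"}.
#' @export
synthetic_spec <- function(T = 300, Q = 2, w_cross = 0.1, w_self = 0.9,
                           D_obs = 10, dyn_lengthscale = 1,
                           obs_lengthscale = 1, noise_var = 1e-4,
                           seed = 1, variant = 0) {
  if (T < 2) stop("T must be at least 2")
  if (w_cross < 0 || w_self < 0) stop("coupling weights must be nonnegative")
  structure(list(T = T, Q = Q, w_cross = w_cross, w_self = w_self,
                 D_obs = D_obs, dyn_lengthscale = dyn_lengthscale,
                 obs_lengthscale = obs_lengthscale, noise_var = noise_var,
                 seed = as.integer(seed), variant = as.integer(variant)),
            class = "synthetic_spec")
}

#' Draw a single consistent function from a GP prior
#'
#' Returns a function handle that can be evaluated sequentially at
#' arbitrary points.  Each new evaluation is drawn from the Gaussian
#' conditional given all previously evaluated points, so the collection of
#' values is one consistent draw from the GP prior; re-evaluating at a
#' previously seen point returns the stored value.
#'
#' @param kernel an \code{\link{ard_se_kernel}} over the input space.
#' @param dim_out number of independent output components.
#' @param seed optional integer seed for the function's own RNG stream,
#'   making the draw reproducible and independent of the ambient RNG.
#' @return a function taking a numeric input vector and returning a
#'   numeric vector of length \code{dim_out}.
#' @export
gp_function_sampler <- function(kernel, dim_out = 1, seed = NULL) {
  env <- new.env(parent = emptyenv())
  env$X <- NULL       # n x Q evaluated inputs
  env$F <- NULL       # n x dim_out values
  env$dim_out <- as.integer(dim_out)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    env$rng <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
  } else {
    env$rng <- NULL
  }
  jit <- 1e-8 * kernel$variance
  function(x) {
    x <- matrix(as.numeric(x), nrow = 1)
    if (!is.null(env$X)) {
      hit <- which(colSums(abs(t(env$X) - c(x))) == 0)
      if (length(hit) > 0) return(env$F[hit[1], ])
    }
    if (is.null(env$X)) {
      cond_mean <- rep(0, env$dim_out)
      cond_var <- kernel$variance
      nprev <- 0
    } else {
      nprev <- nrow(env$X)
      Kxx <- gram(kernel, env$X, jitter = jit)
      ks <- gram(kernel, env$X, x)
      cK <- .safe_chol(Kxx)
      wt <- backsolve(cK, backsolve(cK, ks, transpose = TRUE))
      cond_mean <- crossprod(env$F, wt)
      cond_var <- max(kernel$variance - sum(ks * wt), 0) + jit
    }
    # draw with the sampler's private RNG stream if one was requested
    draw_with_rng <- function(n) {
      if (is.null(env$rng)) return(rnorm(n))
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      assign(".Random.seed", env$rng, globalenv())
      z <- rnorm(n)
      env$rng <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
      z
    }
    z <- draw_with_rng(env$dim_out)
    val <- c(cond_mean) + sqrt(cond_var) * z
    env$X <- rbind(env$X, x)
    env$F <- rbind(env$F, matrix(val, nrow = 1))
    val
  }
}

#' Generate coupled latent trajectories
#'
#' Runs the two-part coupled system forward for \code{spec$T} steps from a
#' small random initial state.  Trajectory 1 is computed without any
#' reference to trajectory 2 (its transition function and RNG stream are
#' seeded separately), so system 1 is autonomous by construction.
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @return list with matrices \code{x1}, \code{x2} (\code{T x Q}) and the
#'   function handles \code{g1}, \code{g2}.
#' @export
make_coupled_latents <- function(spec) {
  Q <- spec$Q
  variant <- spec$variant %||% 0L
  kern <- ard_se_kernel(rep(spec$dyn_lengthscale, Q))
  g1 <- gp_function_sampler(kern, dim_out = Q, seed = spec$seed * 13L + 1L)
  g2 <- gp_function_sampler(kern, dim_out = Q,
                            seed = spec$seed * 13L + 2L + 7919L * variant)
  set.seed(spec$seed * 13L + 3L)
  x1 <- matrix(0, spec$T, Q)
  x2 <- matrix(0, spec$T, Q)
  x1[1, ] <- rnorm(Q, sd = 0.5)
  x2[1, ] <- rnorm(Q, sd = 0.5)
  if (variant > 0L) {
    set.seed(spec$seed * 13L + 6L + variant)
    x2[1, ] <- rnorm(Q, sd = 0.5)
  }
  for (t in 2:spec$T) {
    x1[t, ] <- g1(x1[t - 1, ])
  }
  for (t in 2:spec$T) {
    x2[t, ] <- spec$w_cross * g1(x1[t - 1, ]) + spec$w_self * g2(x2[t - 1, ])
  }
  if (!all(is.finite(x1)) || !all(is.finite(x2))) {
    stop("latent trajectories diverged; try a different seed")
  }
  list(x1 = x1, x2 = x2, g1 = g1, g2 = g2)
}

#' Map latent trajectories to noisy observations
#'
#' For each part, draws \code{spec$D_obs} observed trajectories as
#' independent GP functions (RBF kernel) of that part's latent trajectory
#' and adds isotropic Gaussian noise.
#'
#' @param latents result of \code{\link{make_coupled_latents}} (or any
#'   list of per-part \code{T x Q} matrices under names \code{x1, x2}).
#' @param spec a \code{\link{synthetic_spec}}.
#' @return a \code{\link{trajectory_set}} with one sequence and a
#'   two-part column map.
#' @export
make_observations <- function(latents, spec) {
  set.seed(spec$seed * 13L + 4L)
  obs <- lapply(list(latents$x1, latents$x2), function(X) {
    kern <- ard_se_kernel(rep(spec$obs_lengthscale, ncol(X)))
    K <- gram(kern, X, jitter = 1e-8)
    U <- .safe_chol(K)
    Y <- crossprod(U, matrix(rnorm(nrow(X) * spec$D_obs), nrow(X)))
    Y + matrix(rnorm(length(Y), sd = sqrt(spec$noise_var)), nrow(Y))
  })
  Y <- cbind(obs[[1]], obs[[2]])
  colnames(Y) <- c(paste0("p1_", seq_len(spec$D_obs)),
                   paste0("p2_", seq_len(spec$D_obs)))
  trajectory_set(list(Y), column_map = rep(1:2, each = spec$D_obs))
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper: latents plus observations, with the ground-truth
#' coupling weights attached as metadata.  With \code{trials > 1} the
#' system is run for \code{trials * T} steps and split into consecutive
#' trials, so all trials come from the same pair of transition functions.
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @param trials number of trajectories to generate (default 1).
#' @return a \code{\link{trajectory_set}} with attributes
#'   \code{ground_truth} (weights, seed) and \code{latents}.
#' @export
make_synthetic_dataset <- function(spec, trials = 1) {
  long <- spec
  long$T <- spec$T * trials
  lat <- make_coupled_latents(long)
  ts <- make_observations(lat, long)
  Y <- ts$sequences[[1]]
  seqs <- lapply(seq_len(trials), function(k) {
    Y[(k - 1) * spec$T + seq_len(spec$T), , drop = FALSE]
  })
  out <- trajectory_set(seqs, column_map = ts$column_map)
  attr(out, "ground_truth") <- list(w_cross = spec$w_cross,
                                    w_self = spec$w_self, seed = spec$seed)
  attr(out, "latents") <- list(x1 = lat$x1, x2 = lat$x2)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
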