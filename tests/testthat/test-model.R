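test_that("the ELBO decomposes into kinematics terms plus the dynamics bound", {
  set.seed(31)
  ts <- small_synth(T = 40, seed = 3)
  m <- small_model(ts)
  e <- elbo(m, ts, components = TRUE)
  expect_equal(e$total, sum(e$kinematics) + e$dynamics$total)
  # dynamics decomposition: per-part terms + initial prior + entropy
  expect_equal(e$dynamics$total,
               sum(e$dynamics$per_part) + e$dynamics$initial +
                 e$dynamics$entropy)
  # cross-check the summands against the standalone module functions
  kin1 <- collapsed_bound(
    sweep(ts$sequences[[1]][, m$parts[[1]]$cols], 2, m$parts[[1]]$center),
    m$parts[[1]]$kin_kernel, m$parts[[1]]$kin_Z, m$parts[[1]]$latent,
    m$parts[[1]]$beta)
  expect_equal(e$kinematics[1], kin1)
  expect_equal(e$dynamics$entropy,
               entropy(lapply(m$parts, `[[`, "latent")))
})

test_that("a single-part model reproduces the dedicated vGPDM path", {
  set.seed(32)
  ts <- small_synth(T = 40, seed = 4)
  ts1 <- trajectory_set(lapply(ts$sequences, function(s) {
    s[, 1:10, drop = FALSE]
  }), rep(1, 10))
  m1 <- small_model(ts1)
  expect_equal(elbo(m1, ts1), vgpdm_elbo(m1, ts1), tolerance = 1e-12)
})

test_that("the analytic ELBO gradient agrees with finite differences", {
  set.seed(33)
  ts <- small_synth(T = 30, seed = 5)
  m <- perturb_model(small_model(ts), seed = 34)
  g <- vcgpdm:::.elbo_grad(m, ts)
  expect_equal(g$value, elbo(m, ts))
  slots <- vcgpdm:::.param_slots(m, c("latents", "hypers", "alphas",
                                      "inducing"))
  par0 <- vcgpdm:::.pack_params(m, slots)
  an <- vcgpdm:::.pack_grad(m, g, slots)
  idxs <- sample(length(par0), 20)
  # relative error with a unit floor: gradients below ~1 on this packed
  # scale sit at the finite-difference noise floor of an ELBO of
  # magnitude 1e3-1e4 and are compared absolutely
  errs <- vapply(idxs, function(i) {
    h <- 1e-3
    pp <- par0; pp[i] <- pp[i] + h
    pm <- par0; pm[i] <- pm[i] - h
    fd <- (elbo(vcgpdm:::.unpack_params(m, pp, slots), ts) -
             elbo(vcgpdm:::.unpack_params(m, pm, slots), ts)) / (2 * h)
    abs(fd - an[i]) / max(abs(fd), abs(an[i]), 1)
  }, numeric(1))
  expect_lt(max(errs), 1e-4)
})

test_that("severing couplings with huge alphas makes part terms independent", {
  set.seed(34)
  ts <- small_synth(T = 40, seed = 6)
  m <- small_model(ts)
  # sever both cross couplings
  for (pair in list(c(1, 2), c(2, 1))) {
    cp <- m$couplings[[pair[1]]][[pair[2]]]
    m$couplings[[pair[1]]][[pair[2]]] <-
      coupling_gp(pair[1], pair[2], cp$kernel, cp$inducing, 1e8)
  }
  e <- elbo(m, ts, components = TRUE)
  # each part's dynamics term equals a standalone single-part model's
  for (i in 1:2) {
    ts_i <- trajectory_set(lapply(ts$sequences, function(s) {
      s[, m$parts[[i]]$cols, drop = FALSE]
    }), rep(1, m$parts[[i]]$D))
    mi <- vcgpdm(rep(1, m$parts[[i]]$D), 2, 4, 5)
    mi$parts[[1]] <- m$parts[[i]]
    mi$parts[[1]]$cols <- seq_len(m$parts[[i]]$D)
    mi$couplings[[1]][[1]] <- m$couplings[[i]][[i]]
    mi$couplings[[1]][[1]]$source <- 1L
    mi$couplings[[1]][[1]]$target <- 1L
    ei <- elbo(mi, ts_i, components = TRUE)
    expect_equal(e$dynamics$per_part[i], ei$dynamics$per_part[1],
                 tolerance = 1e-4)
    expect_equal(e$kinematics[i], ei$kinematics[1])
  }
})

test_that("the ELBO is invariant under joint part and column permutation", {
  set.seed(35)
  ts <- small_synth(T = 40, seed = 7)
  m <- small_model(ts)
  e <- elbo(m, ts)
  # swap the two parts and reorder the observed columns accordingly
  perm <- c(m$parts[[2]]$cols, m$parts[[1]]$cols)
  ts2 <- trajectory_set(lapply(ts$sequences, function(s) s[, perm]),
                        rep(1:2, c(m$parts[[2]]$D, m$parts[[1]]$D)))
  m2 <- m
  m2$parts <- list(m$parts[[2]], m$parts[[1]])
  m2$parts[[1]]$cols <- seq_len(m$parts[[2]]$D)
  m2$parts[[2]]$cols <- m$parts[[2]]$D + seq_len(m$parts[[1]]$D)
  m2$column_map <- rep(1:2, c(m$parts[[2]]$D, m$parts[[1]]$D))
  m2$couplings <- lapply(1:2, function(i) lapply(1:2, function(j) {
    cp <- m$couplings[[3 - i]][[3 - j]]
    coupling_gp(i, j, cp$kernel, cp$inducing, cp$alpha)
  }))
  expect_equal(elbo(m2, ts2), e, tolerance = 1e-12)
})

test_that("archives round-trip the model exactly and stay small", {
  set.seed(36)
  ts <- small_synth(T = 40, seed = 8)
  m <- update_posteriors(small_model(ts), ts)
  p <- withr::local_tempfile(fileext = ".json")
  save_vcgpdm(m, p, latents = TRUE)
  m2 <- load_vcgpdm(p)
  m2$seq_id <- m$seq_id
  expect_identical(elbo(m2, ts), elbo(m, ts))
  # archive without latents: size independent of training length
  ts_long <- small_synth(T = 120, seed = 8)
  m_long <- update_posteriors(small_model(ts_long), ts_long)
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  save_vcgpdm(m, p1, latents = FALSE)
  save_vcgpdm(m_long, p2, latents = FALSE)
  expect_lt(abs(file.size(p1) - file.size(p2)) / file.size(p1), 0.02)
})

test_that("composing a model from its own parts reproduces its ELBO", {
  set.seed(37)
  ts <- small_synth(T = 40, seed = 9)
  m <- small_model(ts)
  mc <- vcgpdm_compose(m$parts, m$couplings, ts$column_map, order = m$order)
  mc$seq_id <- m$seq_id
  expect_identical(elbo(mc, ts), elbo(m, ts))
  # frozen components are excluded from the trainable parameter set
  mf <- vcgpdm_compose(m$parts, m$couplings, ts$column_map, order = m$order,
                       fixed_parts = c(TRUE, FALSE),
                       fixed_couplings = matrix(c(TRUE, FALSE, FALSE, FALSE),
                                                2, 2))
  n_free <- length(vcgpdm:::.pack_params(
    mf, vcgpdm:::.param_slots(mf, c("hypers", "inducing"))))
  n_all <- length(vcgpdm:::.pack_params(
    m, vcgpdm:::.param_slots(m, c("hypers", "inducing"))))
  expect_lt(n_free, n_all)
})

test_that("archives of models sharing a part share that part's bytes", {
  set.seed(38)
  ts <- small_synth(T = 40, seed = 10)
  m <- update_posteriors(small_model(ts), ts)
  # variant: different upper part, same lower part
  m2 <- m
  m2$parts[[2]]$beta <- m2$parts[[2]]$beta * 2
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  save_vcgpdm(m, p1)
  save_vcgpdm(m2, p2)
  part1_of <- function(path) {
    jsonlite::toJSON(jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                                        simplifyMatrix = TRUE)$parts[[1]],
                     digits = I(17), auto_unbox = TRUE)
  }
  expect_identical(part1_of(p1), part1_of(p2))
})
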