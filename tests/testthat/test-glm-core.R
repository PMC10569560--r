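# Design construction, likelihood derivatives, MAP fitting, and penalty
# selection for the single-cell Poisson GLM.

# Brute-force design oracle: direct loop over the index arithmetic.
design_oracle <- function(x, y, shape) {
  T_ <- length(x)
  xt <- vapply(seq_len(T_), function(t) {
    idx <- t - (0:(shape$d_stim - 1L))
    sum(x[idx[idx >= 1L]])
  }, numeric(1))
  X <- matrix(0, T_, n_params(shape))
  for (t in seq_len(T_)) {
    for (tau in 0:(shape$T_stim - 1L)) {
      s <- t - tau * shape$d_stim
      X[t, tau + 1L] <- if (s >= 1L) xt[s] else 0
    }
    for (tau in seq_len(shape$T_self)) {
      s <- t - tau
      X[t, shape$T_stim + tau] <- if (s >= 1L) y[s] else 0
    }
    X[t, n_params(shape)] <- 1
  }
  X
}

test_that("design matrix matches the brute-force index oracle", {
  shape <- model_shape(T_stim = 3L, T_self = 2L, d_stim = 2L)
  withr::with_seed(11, {
    x <- rnorm(50); y <- rpois(50, 0.5)
  })
  X <- build_design(x, y, shape)
  expect_equal(unclass(X), design_oracle(x, y, shape),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("zero-padding and box prefilter behave at the edges", {
  shape <- model_shape(T_stim = 4L, T_self = 3L, d_stim = 5L)
  x <- rep(2, 60); y <- c(1, rep(0, 59))
  X <- build_design(x, y, shape)
  # at t = 1 all history columns are zero except the current prefiltered bin
  expect_identical(X[1, 2:(n_params(shape) - 1L)], rep(0, n_params(shape) - 2L))
  # constant stimulus: prefiltered value is c * d_stim for t >= d_stim
  expect_equal(X[shape$d_stim:60, 1], rep(2 * 5, 61 - shape$d_stim))
  # self column tau holds y(t - tau)
  expect_equal(X[3, shape$T_stim + 2L], 1)
})

test_that("log-likelihood value, gradient and hessian are correct", {
  shape <- model_shape(T_stim = 3L, T_self = 2L, d_stim = 2L)
  # all-zero parameters and spikes: rate 1 per bin, loglik = -T
  X0 <- build_design(rnorm(10), rep(0, 10), shape)
  expect_equal(as.numeric(poisson_loglik(rep(0, 6), X0, rep(0, 10))), -10)
  # finite-difference oracle on a random small instance
  withr::with_seed(5, {
    x <- rnorm(40); y <- rpois(40, 0.8); beta <- rnorm(6, sd = 0.2)
  })
  X <- build_design(x, y, shape)
  ll <- poisson_loglik(beta, X, y, gradient = TRUE, hessian = TRUE)
  g <- attr(ll, "gradient"); H <- attr(ll, "hessian")
  eps <- 1e-6
  g_fd <- vapply(seq_along(beta), function(j) {
    e <- numeric(6); e[j] <- eps
    (as.numeric(poisson_loglik(beta + e, X, y)) -
       as.numeric(poisson_loglik(beta - e, X, y))) / (2 * eps)
  }, numeric(1))
  expect_equal(g, g_fd, tolerance = 1e-5)
  H_fd <- vapply(seq_along(beta), function(j) {
    e <- numeric(6); e[j] <- eps
    (attr(poisson_loglik(beta + e, X, y, gradient = TRUE), "gradient") -
       attr(poisson_loglik(beta - e, X, y, gradient = TRUE), "gradient")) /
      (2 * eps)
  }, numeric(6))
  expect_equal(H, H_fd, tolerance = 1e-4)
})

test_that("near-infinite penalties force filters to zero, offset to log(mean)", {
  withr::with_seed(9, {
    x <- rnorm(500); y <- rpois(500, 0.3)
  })
  shape <- model_shape(T_stim = 4L, T_self = 4L, d_stim = 2L)
  b <- fit_glm(x, y, shape, reg_weights(1e6, 1e6))
  expect_lt(max(abs(c(b$beta_stim, b$beta_self))), 1e-4)
  expect_equal(b$beta0, log(mean(y)), tolerance = 1e-4)
})

test_that("the penalized objective has a unique optimum (start-independent)", {
  withr::with_seed(13, {
    x <- rnorm(300); y <- rpois(300, 0.5)
  })
  shape <- model_shape(T_stim = 3L, T_self = 3L, d_stim = 2L)
  reg <- reg_weights(1e-3, 1e-3)
  b1 <- fit_glm(x, y, shape, reg)
  b2 <- fit_glm(x, y, shape, reg,
                init = withr::with_seed(1, rnorm(n_params(shape), sd = 0.5)))
  expect_equal(as.vector(b1), as.vector(b2), tolerance = 1e-6)
})

test_that("fit_glm recovers generating parameters at long T", {
  shape <- model_shape()
  truth <- glm_params(default_stim_filter(), default_cluster_means(3)[2, ], -5)
  x <- gen_pink_noise(60000L, seed = 21)
  y <- simulate_spikes(truth, x, shape, seed = 22)
  expect_false(attr(y, "degenerate"))
  b <- fit_glm(x, as.numeric(y), shape, reg_weights(1e-6, 1e-6))
  expect_lt(rms_filter(as.vector(truth), as.vector(b)), 0.2)
})

test_that("zero-spike neurons stay well-posed via the offset guard", {
  x <- rnorm(200); y <- rep(0, 200)
  b <- fit_glm(x, y, model_shape(3L, 3L, 2L), reg_weights(1e-2, 1e-2))
  # the unregularized intercept MLE is -Inf; the fit must stay finite, with
  # the offset no lower than the box bound
  expect_true(all(is.finite(as.vector(b))))
  expect_gte(b$beta0, -30)
  expect_lt(b$beta0, -10)
})

test_that("cross-validated penalty selection matches an independent scorer", {
  ds <- small_sim(K = 1L, n_per_cluster = 2L, T_ = 800L, n_trials = 2L,
                  seed = 5L)$dataset
  shape <- model_shape(T_stim = 4L, T_self = 6L, d_stim = 5L)
  sel <- select_lambdas(ds, shape, grid_size = 2L)
  scores <- attr(sel, "scores")
  # independent re-computation of V_ALL at each grid point
  N <- length(ds$neurons)
  for (g in seq_len(nrow(scores))) {
    reg <- reg_weights(scores$lambda_stim[g], scores$lambda_self[g])
    v <- 0
    for (i in seq_len(N)) {
      rec <- ds$neurons[[i]]
      T_i <- length(rec$spikes)
      for (l in 1:2) {
        held <- seq(rec$partitions[l, 1], rec$partitions[l, 2])
        tr <- setdiff(seq_len(T_i), held)
        Xfull <- build_design(rec$stimulus, rec$spikes, shape)
        bfit <- spiketypes:::newton_poisson(
          Xfull[tr, ], rec$spikes[tr],
          spiketypes:::penalty_vector(reg, shape), T_norm = length(tr))
        v <- v + as.numeric(poisson_loglik(
          as.numeric(bfit), Xfull[held, ], rec$spikes[held])) / (N * T_i)
      }
    }
    expect_equal(scores$cvll[g], v, tolerance = 1e-6)
  }
  expect_equal(max(scores$cvll), scores$cvll[
    scores$lambda_stim == sel$lambda_stim &
      scores$lambda_self == sel$lambda_self])
})

test_that("a one-point grid is returned as-is", {
  ds <- small_sim(K = 1L, n_per_cluster = 2L, T_ = 800L, n_trials = 2L,
                  seed = 5L)$dataset
  sel <- select_lambdas(ds, model_shape(4L, 6L, 5L), grid_size = 1L,
                        lambda_range = c(1e-3, 1e-3))
  expect_equal(sel$lambda_stim, 1e-3)
  expect_equal(sel$lambda_self, 1e-3)
})

test_that("self-dependent data drives lambda_self small and lambda_stim large", {
  # spiking driven purely by self-history (no stimulus dependence)
  shape <- model_shape(T_stim = 3L, T_self = 5L, d_stim = 2L)
  truth <- glm_params(rep(0, 3), c(-4, 0.7, 0.5, 0.2, -0.2), -3.2)
  x <- gen_pink_noise(6000L, seed = 31)
  y <- simulate_spikes(truth, x, shape, seed = 32)
  expect_false(attr(y, "degenerate"))
  y <- as.numeric(y)
  rec <- neuron_record("n1", x, y,
                       partitions = cbind(c(1L, 3001L), c(3000L, 6000L)))
  ds <- spike_dataset(list(rec))
  sel <- select_lambdas(ds, shape, grid_size = 3L)
  expect_gt(sel$lambda_stim, sel$lambda_self)
})
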