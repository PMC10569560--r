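# Hierarchical EM: joint density, Laplace E-step, closed-form M-step, latent
# estimates, and the full fitting loop.

make_test_omega <- function(shape, K = 2L, seed = 31L) {
  withr::with_seed(seed, {
    cluster_model(rep(1 / K, K),
                  matrix(rnorm(K * shape$T_self, sd = 0.5), K),
                  matrix(runif(K * shape$T_self, 0.05, 0.4), K),
                  lambda_stim = 2)
  })
}

test_that("joint log-density decomposes into likelihood plus priors", {
  shape <- model_shape(3L, 4L, 2L)
  withr::with_seed(17, {
    rec <- neuron_record("n1", rnorm(60), rpois(60, 0.3))
    beta <- glm_params(rnorm(3, sd = 0.3), rnorm(4, sd = 0.3), -1)
  })
  omega <- make_test_omega(shape)
  X <- build_design(rec$stimulus, rec$spikes, shape)
  ll <- as.numeric(poisson_loglik(beta, X, rec$spikes))
  for (k in 1:2) {
    prior_stim <- sum(stats::dnorm(beta$beta_stim, 0,
                                   sqrt(1 / omega$lambda_stim), log = TRUE))
    prior_self <- sum(stats::dnorm(beta$beta_self, omega$mu_self[k, ],
                                   sqrt(omega$sigma_self[k, ]), log = TRUE))
    expect_equal(joint_logdensity(k, beta, rec, omega, shape),
                 ll + prior_stim + prior_self + log(omega$pi[k]),
                 tolerance = 1e-10)
  }
  # zero-weight cluster: -Inf, not an error
  omega0 <- omega; omega0$pi <- c(1, 0)
  expect_identical(joint_logdensity(2L, beta, rec, omega0, shape), -Inf)
})

test_that("joint density gradient matches finite differences", {
  shape <- model_shape(3L, 4L, 2L)
  withr::with_seed(18, {
    rec <- neuron_record("n1", rnorm(50), rpois(50, 0.4))
    beta <- rnorm(n_params(shape), sd = 0.2)
  })
  omega <- make_test_omega(shape)
  pr <- spiketypes:::prior_for_cluster(omega, 1L, shape)
  X <- build_design(rec$stimulus, rec$spikes, shape)
  fn <- spiketypes:::make_joint_fn(X, rec$spikes, pr$prec, pr$pmean,
                                   log(omega$pi[1]))
  g <- fn(beta)$grad
  eps <- 1e-6
  g_fd <- vapply(seq_along(beta), function(j) {
    e <- numeric(length(beta)); e[j] <- eps
    (fn(beta + e, derivs = FALSE)$value -
       fn(beta - e, derivs = FALSE)$value) / (2 * eps)
  }, numeric(1))
  expect_equal(g, g_fd, tolerance = 1e-5)
})

test_that("Laplace evidence is exact for a Gaussian integrand with diagonal curvature", {
  # synthetic concave quadratic in place of the Poisson term: the integral
  # has a closed form, so log Z must match it to high precision
  withr::with_seed(19, {
    p <- 6L
    a <- runif(p, 0.5, 3)     # diagonal precision of the quadratic
    b <- rnorm(p)
    c0 <- 1.3
  })
  fn <- function(beta, derivs = TRUE) {
    v <- -0.5 * sum(a * beta^2) + sum(b * beta) + c0
    if (!derivs) return(list(value = v))
    list(value = v, grad = -a * beta + b, hess = diag(-a))
  }
  la <- spiketypes:::laplace_fit(fn, init = rep(0, p))
  closed_form <- c0 + 0.5 * sum(b^2 / a) +
    0.5 * p * log(2 * pi) - 0.5 * sum(log(a))
  expect_equal(la$logZ, closed_form, tolerance = 1e-8)
  expect_equal(la$m, b / a, tolerance = 1e-8)
})

test_that("e_step normalizes evidence weights and respects a dominating prior", {
  sim <- small_sim()
  shape <- sim$cfg$shape
  ds <- sim$dataset
  omega <- cluster_model(c(0.5, 0.3, 0.2),
                         default_cluster_means(3L, shape$T_self),
                         matrix(0.2, 3, shape$T_self), lambda_stim = 10)
  post <- e_step(ds, omega, shape)
  expect_lt(max(abs(rowSums(post$Ztilde) - 1)), 1e-10)
  expect_true(all(unlist(post$cvar) > 0))
  # variances at the floor: the prior dominates and the mode's self block
  # collapses onto the cluster mean
  omega_tight <- omega
  omega_tight$sigma_self <- matrix(1e-8, 3, shape$T_self)
  post_t <- e_step(ds, omega_tight, shape)
  self_idx <- shape$T_stim + seq_len(shape$T_self)
  expect_equal(post_t$m[[1]][self_idx, 2], omega$mu_self[2, ],
               tolerance = 1e-3)
})

test_that("m_step matches a direct-summation oracle", {
  shape <- model_shape(2L, 3L, 1L)
  p <- n_params(shape)
  N <- 7L; K <- 2L
  withr::with_seed(20, {
    logZ <- matrix(rnorm(N * K), N, K)
    m <- lapply(seq_len(N), function(i) matrix(rnorm(p * K), p, K))
    cvar <- lapply(seq_len(N), function(i)
      matrix(runif(p * K, 0.01, 0.5), p, K))
  })
  lse <- apply(logZ, 1L, spiketypes:::logsumexp)
  post <- structure(list(logZ = logZ, Ztilde = exp(logZ - lse), m = m,
                         cvar = cvar, shape = shape),
                    class = "posterior_approx")
  omega_in <- make_test_omega(shape, K = 2L)
  up <- m_step(post, omega_in)
  W <- exp(logZ - lse)
  self_idx <- shape$T_stim + seq_len(shape$T_self)
  for (k in seq_len(K)) {
    Nk <- sum(W[, k])
    expect_equal(up$pi[k], Nk / N, tolerance = 1e-12)
    mu_o <- Reduce(`+`, lapply(seq_len(N), function(i)
      W[i, k] * m[[i]][self_idx, k])) / Nk
    expect_equal(up$mu_self[k, ], mu_o, tolerance = 1e-12)
    sig_o <- Reduce(`+`, lapply(seq_len(N), function(i)
      W[i, k] * (cvar[[i]][self_idx, k] + m[[i]][self_idx, k]^2))) / Nk -
      mu_o^2
    expect_equal(up$sigma_self[k, ], pmax(sig_o, 1e-8), tolerance = 1e-12)
  }
  expect_equal(sum(up$pi), 1, tolerance = 1e-12)
})

test_that("K = 1 m_step is the unweighted closed form", {
  shape <- model_shape(2L, 2L, 1L)
  p <- n_params(shape)
  withr::with_seed(21, {
    m <- lapply(1:5, function(i) matrix(rnorm(p), p, 1))
    cvar <- lapply(1:5, function(i) matrix(runif(p, 0.1, 1), p, 1))
  })
  post <- structure(list(logZ = matrix(0, 5, 1), Ztilde = matrix(1, 5, 1),
                         m = m, cvar = cvar, shape = shape),
                    class = "posterior_approx")
  omega_in <- cluster_model(1, matrix(0, 1, 2), matrix(1, 1, 2),
                            lambda_stim = 1)
  up <- m_step(post, omega_in)
  self_idx <- 3:4
  M <- t(sapply(m, function(x) x[self_idx, 1]))
  C <- t(sapply(cvar, function(x) x[self_idx, 1]))
  expect_equal(up$mu_self[1, ], colMeans(M), tolerance = 1e-12)
  expect_equal(up$sigma_self[1, ], colMeans(C + M^2) - colMeans(M)^2,
               tolerance = 1e-12)
})

test_that("estimate_latents takes the argmax evidence with ties to lowest k", {
  shape <- model_shape(1L, 1L, 1L)
  m <- list(matrix(1:3, 3, 2)[, c(1, 1)] * 1.0)
  m[[1]][, 2] <- c(9, 9, 9)
  post <- structure(list(logZ = rbind(c(log(0.1), log(0.9))),
                         Ztilde = rbind(c(0.1, 0.9)), m = m,
                         cvar = list(matrix(1, 3, 2)), shape = shape),
                    class = "posterior_approx")
  lat <- estimate_latents(post)
  expect_identical(lat$labels, 2L)
  expect_identical(as.vector(lat$betas[[1]]), c(9, 9, 9))
  post$logZ <- rbind(c(0.5, 0.5))   # exact tie -> lowest index
  expect_identical(estimate_latents(post)$labels, 1L)
})

test_that("the EM objective ascends and the fit is deterministic", {
  sim <- small_sim()
  fit <- fit_simultaneous(sim$dataset, sim$cfg$shape, K = 3L,
                          lambda_stim = 10, n_restarts = 1L, seed = 4L,
                          max_iter = 40L)
  # approximate-EM ascent: no decrease beyond the tolerance, ever
  expect_identical(fit$n_obj_decreases, 0L)
  expect_true(all(diff(fit$ll_trace) > -1e-6 * abs(fit$ll_trace[-1])))
  expect_lt(fit$max_ztilde_dev, 1e-10)
  # labels equal the evidence argmax and betas equal the winning modes
  expect_identical(fit$labels, max.col(fit$posterior$logZ,
                                       ties.method = "first"))
  for (i in c(1L, 5L)) {
    expect_identical(as.vector(fit$betas[[i]]),
                     fit$posterior$m[[i]][, fit$labels[i]])
  }
  fit2 <- fit_simultaneous(sim$dataset, sim$cfg$shape, K = 3L,
                           lambda_stim = 10, n_restarts = 1L, seed = 4L,
                           max_iter = 40L)
  expect_equal(fit$ll_per_neuron, fit2$ll_per_neuron, tolerance = 0)
  expect_identical(fit$labels, fit2$labels)
})

test_that("K = 1 reduces to MAP fitting with a learned shared prior", {
  sim <- small_sim(K = 1L, n_per_cluster = 5L, T_ = 1000L)
  fit <- fit_simultaneous(sim$dataset, sim$cfg$shape, K = 1L,
                          lambda_stim = 10, n_restarts = 1L, seed = 2L,
                          max_iter = 30L)
  expect_true(all(fit$labels == 1L))
  expect_equal(fit$omega$pi, 1)
})

test_that("cluster permutation leaves total evidence unchanged, permutes labels", {
  sim <- small_sim()
  shape <- sim$cfg$shape
  omega <- cluster_model(c(0.5, 0.3, 0.2),
                         default_cluster_means(3L, shape$T_self),
                         matrix(0.1, 3, shape$T_self), lambda_stim = 10)
  perm <- c(2L, 3L, 1L)
  omega_p <- cluster_model(omega$pi[perm], omega$mu_self[perm, ],
                           omega$sigma_self[perm, ], lambda_stim = 10)
  post <- e_step(sim$dataset, omega, shape)
  post_p <- e_step(sim$dataset, omega_p, shape)
  ll <- apply(post$logZ, 1L, spiketypes:::logsumexp)
  ll_p <- apply(post_p$logZ, 1L, spiketypes:::logsumexp)
  expect_equal(ll, ll_p, tolerance = 1e-10)
  lab <- estimate_latents(post)$labels
  lab_p <- estimate_latents(post_p)$labels
  expect_identical(order(perm)[lab], lab_p)
})
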