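# Simultaneous method: EM for the hierarchical generative model in which each
# neuron's GLM parameters are latent draws from a cell-type-specific Gaussian.
# The E-step builds a per-(neuron, cluster) weighted-Gaussian (Laplace)
# approximation -- mode, diagonal curvature, and evidence weight -- and the
# M-step updates the mixture weights, self-filter means, and (diagonal)
# covariances in closed form.

# --- generic Laplace machinery -------------------------------------------

# Maximize a smooth concave log-density given by a closure
# fn(beta, derivs = TRUE) -> list(value, grad, hess), by damped Newton.
newton_generic <- function(fn, init, tol = 1e-6, max_iter = 100L) {
  beta <- init
  ev <- fn(beta)
  for (it in seq_len(max_iter)) {
    g <- ev$grad
    if (max(abs(g)) < tol)
      return(list(beta = beta, ev = ev, converged = TRUE, iterations = it))
    H <- -ev$hess                      # positive definite for concave fn
    step <- tryCatch(solve(H, g), error = function(e)
      solve(H + diag(1e-8 * max(diag(H)), length(g)), g))
    alpha <- 1
    repeat {
      cand <- beta + alpha * step
      ev_cand <- fn(cand)
      if (is.finite(ev_cand$value) && ev_cand$value >= ev$value) break
      alpha <- alpha / 2
      if (alpha < 1e-12) { cand <- beta; ev_cand <- ev; break }
    }
    if (identical(cand, beta))
      return(list(beta = beta, ev = ev, converged = max(abs(g)) < 1e2 * tol,
                  iterations = it))
    beta <- cand; ev <- ev_cand
  }
  list(beta = beta, ev = fn(beta), converged = FALSE, iterations = max_iter)
}

# Laplace approximation of the integral of exp(fn) over beta: find the mode,
# take the diagonal of the Hessian there (as the algorithm prescribes -- not
# the diagonal of the full inverse), and return
#   log Z = fn(mode) + (dim/2) log 2pi + (1/2) sum(log c),  c = -1/diag(hess).
laplace_fit <- function(fn, init, tol = 1e-6, max_iter = 100L) {
  opt <- newton_generic(fn, init, tol = tol, max_iter = max_iter)
  if (!opt$converged)
    stop("laplace_fit: mode search did not converge")
  hdiag <- -diag(opt$ev$hess)
  if (any(hdiag <= 0))
    stop("laplace_fit: non-positive curvature at the mode")
  cdiag <- 1 / hdiag
  p <- length(init)
  list(m = opt$beta, cdiag = cdiag,
       logZ = opt$ev$value + 0.5 * p * log(2 * pi) + 0.5 * sum(log(cdiag)),
       value = opt$ev$value, iterations = opt$iterations)
}

# --- the hierarchical joint density --------------------------------------

# Per-coordinate prior precision and mean implied by cluster k of omega:
# stimulus coords get the shared zero-mean prior with precision lambda_stim,
# self coords get N(mu_k, Sigma_k), the offset gets a flat prior.
prior_for_cluster <- function(omega, k, shape) {
  prec <- c(rep(omega$lambda_stim, shape$T_stim), 1 / omega$sigma_self[k, ], 0)
  pmean <- c(rep(0, shape$T_stim), omega$mu_self[k, ], 0)
  list(prec = prec, pmean = pmean)
}

# Closure evaluating log P_joint(k, beta, y | x; omega) with derivatives.
# The heavy lifting (linear predictor, gradient, Hessian) is compiled; the
# log(y!) constant can be supplied pre-computed to avoid recomputing it for
# every cluster and EM iteration.
make_joint_fn <- function(X, y, prec, pmean, log_pi, eta_max = ETA_CEILING,
                          lgam = sum(lgamma(y + 1))) {
  pos <- prec > 0
  log_const <- 0.5 * sum(log(prec[pos] / (2 * pi))) + log_pi - lgam
  function(beta, derivs = TRUE) {
    r <- joint_eval_cpp(X, y, beta, prec, pmean, log_const, eta_max, derivs)
    if (derivs) r$grad <- drop(r$grad)
    r
  }
}

#' Log joint density of (cluster, parameters, spikes) for one neuron
#'
#' Evaluates `log[ P_SC(y | x; beta) f(beta_stim; 0, I/lambda_stim)
#' f(beta_self; mu_k, Sigma_k) pi_k ]`. The offset has a flat prior and
#' contributes no prior term. `pi_k = 0` returns `-Inf`.
#'
#' @param k cluster index.
#' @param beta a [glm_params()] or flat parameter vector.
#' @param neuron a [neuron_record()].
#' @param omega a [cluster_model()] with a finite positive `lambda_stim`.
#' @param shape a [model_shape()].
#' @return scalar log joint density.
#' @export
joint_logdensity <- function(k, beta, neuron, omega, shape = model_shape()) {
  if (inherits(beta, "glm_params")) beta <- as.vector(beta)
  stopifnot(k >= 1, k <= omega$K, is.finite(omega$lambda_stim),
            omega$lambda_stim > 0)
  if (omega$pi[k] <= 0) return(-Inf)
  X <- build_design(neuron$stimulus, neuron$spikes, shape)
  pr <- prior_for_cluster(omega, k, shape)
  fn <- make_joint_fn(X, neuron$spikes, pr$prec, pr$pmean, log(omega$pi[k]),
                      eta_max = Inf)
  fn(beta, derivs = FALSE)$value
}

# --- E- and M-steps -------------------------------------------------------

#' E-step: per-(neuron, cluster) Laplace approximations
#'
#' For every neuron `i` and cluster `k`, finds the mode `m_{i,k}` of the joint
#' log-density over `beta` (a concave problem solved by Newton iterations),
#' the diagonal curvature `c_{i,k} = -1/diag(hessian)` at the mode, and the
#' Laplace evidence weight
#' `log Z_{i,k} = log P_joint(m) + (dim/2) log 2pi + (1/2) sum log c`.
#' Weights are normalized across clusters in the log domain.
#'
#' @param ds a [spike_dataset()].
#' @param omega a [cluster_model()] with positive `lambda_stim`.
#' @param shape a [model_shape()].
#' @param warm_starts optional list (length N) of either `p`-vectors or
#'   `p x K` matrices of starting points for the mode searches.
#' @param designs optional pre-built list of design matrices (cached across
#'   EM iterations).
#' @return an object of class `posterior_approx`: `logZ` and `Ztilde`
#'   (`N x K`), `m` and `cvar` (lists of `p x K` matrices).
#' @export
e_step <- function(ds, omega, shape = model_shape(), warm_starts = NULL,
                   designs = NULL) {
  N <- length(ds$neurons); K <- omega$K; p <- n_params(shape)
  if (is.null(designs))
    designs <- lapply(ds$neurons, function(r)
      build_design(r$stimulus, r$spikes, shape))
  logZ <- matrix(NA_real_, N, K)
  m <- vector("list", N); cvar <- vector("list", N)
  log_pi <- log(pmax(omega$pi, 1e-300))
  for (i in seq_len(N)) {
    y <- ds$neurons[[i]]$spikes
    X <- designs[[i]]
    lgam_i <- sum(lgamma(y + 1))
    tol_i <- 1e-6 * max(1, length(y))
    mi <- matrix(0, p, K); ci <- matrix(0, p, K)
    ws <- warm_starts[[i]] %||% NULL
    for (k in seq_len(K)) {
      pr <- prior_for_cluster(omega, k, shape)
      fn <- make_joint_fn(X, y, pr$prec, pr$pmean, log_pi[k], lgam = lgam_i)
      init <- if (is.null(ws)) NULL else if (is.matrix(ws)) ws[, k] else ws
      if (is.null(init)) {
        init <- numeric(p)
        init[p] <- log(max(mean(y), 1e-8))
        init[shape$T_stim + seq_len(shape$T_self)] <- pr$pmean[
          shape$T_stim + seq_len(shape$T_self)]
      }
      la <- tryCatch(laplace_fit(fn, init, tol = tol_i),
                     error = function(e) NULL)
      if (is.null(la)) {
        zero_init <- numeric(p); zero_init[p] <- log(max(mean(y), 1e-8))
        la <- tryCatch(laplace_fit(fn, zero_init, tol = tol_i),
                       error = function(e) NULL)
      }
      if (is.null(la))
        stop(sprintf("e_step: mode search failed for neuron %d, cluster %d",
                     i, k))
      mi[, k] <- la$m; ci[, k] <- la$cdiag; logZ[i, k] <- la$logZ
    }
    m[[i]] <- mi; cvar[[i]] <- ci
  }
  lse <- apply(logZ, 1L, logsumexp)
  structure(list(logZ = logZ, Ztilde = exp(logZ - lse), m = m, cvar = cvar,
                 shape = shape),
            class = "posterior_approx")
}

#' M-step: closed-form update of the cluster model
#'
#' Given the E-step's weighted-Gaussian approximations, updates
#' `pi_k = mean_i Ztilde_{i,k}`,
#' `mu_k = sum_i Ztilde_{i,k} m_{i,k}^self / sum_i Ztilde_{i,k}`, and
#' `Sigma_k = sum_i Ztilde_{i,k} (c_{i,k}^self + m^self o m^self) / sum_i
#' Ztilde_{i,k} - mu_k o mu_k` (elementwise), floored at the variance floor.
#' A cluster whose total responsibility falls below `1e-8` is re-seeded at the
#' mode of the worst-explained neuron with a small weight.
#'
#' @param post a `posterior_approx` from [e_step()].
#' @param omega the current [cluster_model()] (supplies `lambda_stim` and the
#'   re-seeding context).
#' @return the updated [cluster_model()].
#' @export
m_step <- function(post, omega) {
  shape <- post$shape
  N <- nrow(post$logZ); K <- ncol(post$logZ)
  self_idx <- shape$T_stim + seq_len(shape$T_self)
  W <- post$Ztilde
  Nk <- colSums(W)
  mu <- matrix(0, K, shape$T_self); sig <- matrix(VAR_FLOOR, K, shape$T_self)
  reseeded <- integer()
  for (k in seq_len(K)) {
    Mk <- t(vapply(post$m, function(mi) mi[self_idx, k],
                   numeric(shape$T_self)))
    Ck <- t(vapply(post$cvar, function(ci) ci[self_idx, k],
                   numeric(shape$T_self)))
    if (Nk[k] < 1e-8) {
      i_bad <- which.min(apply(post$logZ, 1L, logsumexp))
      mu[k, ] <- Mk[i_bad, ]
      sig[k, ] <- pmax(colMeans(Ck), VAR_FLOOR)
      reseeded <- c(reseeded, k)
      Nk[k] <- 1
      next
    }
    mu[k, ] <- drop(crossprod(W[, k], Mk)) / Nk[k]
    sig[k, ] <- pmax(drop(crossprod(W[, k], Ck + Mk^2)) / Nk[k] - mu[k, ]^2,
                     VAR_FLOOR)
  }
  if (length(reseeded)) {
    warning("m_step: empty cluster(s) re-seeded: ",
            paste(reseeded, collapse = ", "))
    Nk[reseeded] <- 1
  }
  pi_new <- Nk / sum(Nk)
  cluster_model(pi_new, mu, sig, lambda_stim = omega$lambda_stim)
}

#' Point estimates of the latent cluster labels and GLM parameters
#'
#' Labels maximize the evidence weight with the parameters marginalized out
#' (`k_i = argmax_k Z_{i,k}`, ties to the lowest index); the parameter
#' estimate is the corresponding Laplace mode (`beta_i = m_{i, k_i}`).
#'
#' @param post a `posterior_approx` from [e_step()].
#' @return `list(labels, betas)` with `betas` a list of [glm_params()].
#' @export
estimate_latents <- function(post) {
  labels <- max.col(post$logZ, ties.method = "first")
  betas <- lapply(seq_along(labels), function(i)
    params_from_vector(post$m[[i]][, labels[i]], post$shape))
  list(labels = labels, betas = betas)
}

# Apply a cluster permutation consistently to a posterior_approx.
permute_posterior <- function(post, perm) {
  post$logZ <- post$logZ[, perm, drop = FALSE]
  post$Ztilde <- post$Ztilde[, perm, drop = FALSE]
  post$m <- lapply(post$m, function(mi) mi[, perm, drop = FALSE])
  post$cvar <- lapply(post$cvar, function(ci) ci[, perm, drop = FALSE])
  post
}

#' Simultaneous cell-type discovery (hierarchical EM)
#'
#' Fits the hierarchical mixture-of-GLMs by approximate EM. Each restart is
#' initialized from independent per-neuron MAP fits (stimulus prior
#' `lambda_stim`, plus a small fixed ridge on the self filter purely to make
#' the warm-start fits well-posed) followed by a 10-restart GMM on the fitted
#' self filters; EM then alternates [e_step()] and [m_step()].
#'
#' Convergence is declared on the quantities being estimated: iteration stops
#' when the largest relative change of any cluster parameter (weights, means,
#' variances) falls below `tol`, or after `max_iter` iterations. (A criterion
#' on the marginal log-likelihood is unreliable here because that objective is
#' dominated by data-size-dependent constants -- adding recording length
#' inflates it and would stop the variance updates long before the cluster
#' model stabilizes.) The approximate marginal log-likelihood
#' `sum_i log sum_k Z_{i,k}` is still tracked per iteration (`ll_trace`) and
#' selects the best restart. Clusters of the returned model are ordered by
#' descending sum of their self-filter means.
#'
#' @param ds a [spike_dataset()].
#' @param shape a [model_shape()].
#' @param K number of cell types (`N >= K`).
#' @param lambda_stim prior precision of the shared zero-mean stimulus-filter
#'   prior in the joint density.
#' @param n_restarts random initializations (best kept).
#' @param seed master seed.
#' @param max_iter EM iteration cap per restart.
#' @param tol convergence tolerance: largest relative per-iteration change of
#'   any cluster parameter.
#' @param gmm_n_init GMM restarts inside each initialization.
#' @param init_ridge_self small ridge on self filters for the warm-start MAP
#'   fits only (the hierarchical model itself has no self-filter
#'   hyperparameter).
#' @param init_betas optional list of precomputed per-neuron warm-start
#'   parameter vectors (as produced internally); lets a model-selection grid
#'   reuse one set of single-neuron fits across many values of `K`.
#' @param verbose print per-iteration progress.
#' @return a `fit_result` with, additionally, `posterior`, `ll_trace`,
#'   `n_em_iters`, `converged`, `restart_scores`, `n_obj_decreases`,
#'   `max_ztilde_dev`, `lambda_stim`.
#' @export
fit_simultaneous <- function(ds, shape = model_shape(), K, lambda_stim = 1,
                             n_restarts = 20L, seed = 1L, max_iter = 200L,
                             tol = 1e-3, gmm_n_init = 10L,
                             init_ridge_self = 1e-4, init_betas = NULL,
                             verbose = FALSE) {
  validate_dataset(ds)
  N <- length(ds$neurons)
  if (N < K) stop("fit_simultaneous: need at least K neurons")
  stopifnot(lambda_stim > 0)
  p <- n_params(shape)
  designs <- lapply(ds$neurons, function(r)
    build_design(r$stimulus, r$spikes, shape))
  # per-neuron MAP warm starts, shared by all restarts
  if (is.null(init_betas)) {
    init_prec <- c(rep(lambda_stim, shape$T_stim),
                   rep(init_ridge_self, shape$T_self), 0)
    init_betas <- lapply(seq_len(N), function(i) {
      y <- ds$neurons[[i]]$spikes
      fn <- make_joint_fn(designs[[i]], y, init_prec, numeric(p), 0)
      b0 <- numeric(p); b0[p] <- log(max(mean(y), 1e-8))
      newton_generic(fn, b0, tol = 1e-6 * max(1, length(y)),
                     max_iter = 200L)$beta
    })
  }
  B_init <- t(vapply(init_betas, function(b)
    b[shape$T_stim + seq_len(shape$T_self)], numeric(shape$T_self)))

  best <- NULL
  restart_scores <- numeric(n_restarts)
  for (r in seq_len(n_restarts)) {
    gmm0 <- fit_gmm(B_init, K, n_init = gmm_n_init,
                    seed = derive_seed(seed, 1000 + r))
    omega <- cluster_model(gmm0$pi, gmm0$mu_self, gmm0$sigma_self,
                           lambda_stim = lambda_stim)
    warm <- init_betas
    trace <- numeric(0)
    n_dec <- 0L
    zt_dev <- 0
    converged <- FALSE
    post <- NULL
    for (it in seq_len(max_iter)) {
      post <- e_step(ds, omega, shape, warm_starts = warm, designs = designs)
      obj <- sum(apply(post$logZ, 1L, logsumexp))
      zt_dev <- max(zt_dev, max(abs(rowSums(post$Ztilde) - 1)))
      trace <- c(trace, obj)
      if (it > 1L && obj < trace[it - 1L] - 1e-6 * abs(trace[it - 1L]))
        n_dec <- n_dec + 1L
      omega_new <- m_step(post, omega)
      delta <- max(abs(omega_new$pi - omega$pi),
                   abs(omega_new$mu_self - omega$mu_self) /
                     (sqrt(omega$sigma_self) + 1e-8),
                   abs(omega_new$sigma_self / omega$sigma_self - 1))
      if (verbose)
        message(sprintf("restart %d iter %d: obj = %.6f, dpar = %.3g",
                        r, it, obj, delta))
      omega <- omega_new
      warm <- post$m
      if (delta < tol) { converged <- TRUE; break }
    }
    # one final E-step so the posterior matches the returned cluster model
    post <- e_step(ds, omega, shape, warm_starts = warm, designs = designs)
    trace <- c(trace, sum(apply(post$logZ, 1L, logsumexp)))
    restart_scores[r] <- trace[length(trace)]
    if (is.null(best) || restart_scores[r] > best$score)
      best <- list(score = restart_scores[r], omega = omega, post = post,
                   trace = trace, converged = converged, n_dec = n_dec,
                   zt_dev = zt_dev, n_iters = length(trace))
  }

  perm <- cluster_order(best$omega)
  omega <- permute_cluster_model(best$omega, perm)
  omega$loglik <- best$score
  post <- permute_posterior(best$post, perm)
  lat <- estimate_latents(post)
  new_fit_result("simultaneous", omega, lat$labels, lat$betas,
                 ll_per_neuron = apply(post$logZ, 1L, logsumexp),
                 shape = shape, posterior = post, ll_trace = best$trace,
                 n_em_iters = best$n_iters, converged = best$converged,
                 restart_scores = restart_scores,
                 n_obj_decreases = best$n_dec,
                 max_ztilde_dev = best$zt_dev,
                 lambda_stim = lambda_stim, neuron_ids = neuron_ids(ds))
}
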