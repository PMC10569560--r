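# Diagonal-covariance Gaussian mixture model: the cluster model shared by
# both methods. Fitted by EM with k-means initialization and multiple
# restarts, keeping the best-likelihood solution.

# Floor on every mixture-component variance; prevents evidence blow-up when a
# component collapses onto very few points. Shared with the simultaneous
# method's M-step.
VAR_FLOOR <- 1e-8

#' Cluster model (mixture over self-interaction filters)
#'
#' @param pi mixture weights (length `K`, sum to 1).
#' @param mu_self `K x T_self` matrix of component means.
#' @param sigma_self `K x T_self` matrix of component variances (the diagonal
#'   of each diagonal covariance matrix).
#' @param lambda_stim shared stimulus-filter prior precision (used only by the
#'   simultaneous method; `NA` for a plain GMM).
#' @param loglik optional fitted mixture log-likelihood.
#' @return an object of class `cluster_model`.
#' @export
cluster_model <- function(pi, mu_self, sigma_self, lambda_stim = NA_real_,
                          loglik = NA_real_) {
  mu_self <- rbind(mu_self); sigma_self <- rbind(sigma_self)
  K <- length(pi)
  stopifnot(nrow(mu_self) == K, all(dim(sigma_self) == dim(mu_self)),
            all(pi >= 0), abs(sum(pi) - 1) < 1e-12,
            all(sigma_self >= VAR_FLOOR / 2))
  structure(list(K = K, pi = as.numeric(pi), mu_self = mu_self,
                 sigma_self = sigma_self, lambda_stim = lambda_stim,
                 loglik = loglik),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> K = %d, dim = %d, loglik = %s\n", x$K,
              ncol(x$mu_self), format(x$loglik)))
  cat("pi:", format(round(x$pi, 4)), "\n")
  invisible(x)
}

# N x K matrix of per-component Gaussian log-densities under diagonal
# covariances.
gauss_logdens <- function(B, mu, sigma2) {
  K <- nrow(mu)
  ld <- matrix(0, nrow(B), K)
  for (k in seq_len(K)) {
    d2 <- sweep(B, 2L, mu[k, ])^2
    ld[, k] <- -0.5 * (drop(d2 %*% (1 / sigma2[k, ])) +
                         sum(log(2 * pi * sigma2[k, ])))
  }
  ld
}

# N x K log of pi_k * f(b_i; mu_k, Sigma_k).
component_logscores <- function(B, model) {
  sweep(gauss_logdens(B, model$mu_self, model$sigma_self), 2L,
        log(model$pi), `+`)
}

#' Per-point mixture log-density under a cluster model
#' @param B `N x T_self` matrix of filters.
#' @param model a [cluster_model()].
#' @return numeric vector `log sum_k pi_k f(b_i; mu_k, Sigma_k)`.
#' @export
gmm_loglik <- function(B, model) {
  apply(component_logscores(rbind(B), model), 1L, logsumexp)
}

# One EM run from given initial parameters; returns model + loglik.
gmm_em <- function(B, pi, mu, sigma2, tol = 1e-8, max_iter = 500L) {
  N <- nrow(B)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    sc <- sweep(gauss_logdens(B, mu, sigma2), 2L, log(pmax(pi, 1e-300)), `+`)
    lse <- apply(sc, 1L, logsumexp)
    ll <- sum(lse)
    r <- exp(sc - lse)
    Nk <- colSums(r)
    if (any(Nk < 1e-10)) {
      # degenerate component: re-seed at the worst-explained point
      for (k in which(Nk < 1e-10)) {
        i_bad <- which.min(lse)
        mu[k, ] <- B[i_bad, ]
        sigma2[k, ] <- pmax(apply(B, 2L, stats::var), VAR_FLOOR)
        Nk[k] <- 1
      }
      warning("gmm_em: degenerate component re-seeded")
    }
    pi <- Nk / sum(Nk)
    mu <- crossprod(r, B) / Nk
    sigma2 <- pmax(crossprod(r, B^2) / Nk - mu^2, VAR_FLOOR)
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * (abs(ll) + 1)) break
    ll_old <- ll
  }
  list(pi = pi, mu = mu, sigma2 = sigma2, loglik = ll)
}

#' Fit a diagonal-covariance GMM to fitted self-interaction filters
#'
#' EM with k-means initialization, restarted `n_init` times from different
#' seeds; the restart with the highest mixture log-likelihood is returned.
#' Component variances are floored at `1e-8`.
#'
#' @param betas_self `N x T_self` matrix (or list of vectors) of filters.
#' @param K number of components (`N >= K`).
#' @param n_init number of random restarts.
#' @param seed master seed; per-restart seeds are derived from it.
#' @return a [cluster_model()] with element `loglik`.
#' @export
fit_gmm <- function(betas_self, K, n_init = 20L, seed = 1L) {
  B <- if (is.list(betas_self)) do.call(rbind, betas_self) else rbind(betas_self)
  N <- nrow(B)
  if (N < K) stop("fit_gmm: need at least K points (N = ", N, ", K = ", K, ")")
  best <- NULL
  for (r in seq_len(n_init)) {
    init <- withr::with_seed(derive_seed(seed, r), {
      km <- tryCatch(
        stats::kmeans(B, centers = K, nstart = 1L, iter.max = 50L),
        error = function(e) NULL)
      if (is.null(km)) {
        idx <- sample.int(N, K)
        list(centers = B[idx, , drop = FALSE],
             cluster = apply(as.matrix(stats::dist(B))[, idx, drop = FALSE],
                             1L, which.min))
      } else list(centers = km$centers, cluster = km$cluster)
    })
    pi0 <- tabulate(init$cluster, K) / N
    pi0 <- pmax(pi0, 1 / (10 * N)); pi0 <- pi0 / sum(pi0)
    sigma0 <- matrix(VAR_FLOOR, K, ncol(B))
    for (k in seq_len(K)) {
      pts <- B[init$cluster == k, , drop = FALSE]
      v <- if (nrow(pts) > 1L) apply(pts, 2L, stats::var) else
        apply(B, 2L, stats::var) / K
      sigma0[k, ] <- pmax(v, VAR_FLOOR)
    }
    fit <- gmm_em(B, pi0, init$centers, sigma0)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  cluster_model(best$pi, best$mu, best$sigma2, loglik = best$loglik)
}

#' Maximum-likelihood cell-type assignment under a cluster model
#'
#' Assigns each filter to `argmax_k pi_k f(b; mu_k, Sigma_k)`; ties break to
#' the lowest cluster index.
#'
#' @param betas_self `N x T_self` matrix (or list) of filters.
#' @param model a [cluster_model()].
#' @return integer labels in `1..K`.
#' @export
assign_types <- function(betas_self, model) {
  B <- if (is.list(betas_self)) do.call(rbind, betas_self) else rbind(betas_self)
  if (ncol(B) != ncol(model$mu_self))
    stop("assign_types: filter dimension does not match the model")
  max.col(component_logscores(B, model), ties.method = "first")
}
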