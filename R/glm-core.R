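# The single-cell Poisson GLM: design construction, log-likelihood with
# derivatives, penalized (MAP) fitting, and cross-validated selection of the
# ridge penalties.

#' Build the GLM design matrix for one neuron
#'
#' Columns are, in order: `T_stim` stimulus-history columns on the
#' box-prefiltered, downsampled stimulus; `T_self` spike-history columns; and
#' a constant 1. The prefiltered stimulus is
#' `xt(t) = sum_{s=0}^{d_stim-1} x(t-s)` and stimulus column `tau+1` at row
#' `t` holds `xt(t - tau*d_stim)`; self column `tau` at row `t` holds
#' `y(t - tau)`. Indices before the start of the recording are zero
#' (zero-padding).
#'
#' @param x stimulus vector.
#' @param y spike-count vector (same length).
#' @param shape a [model_shape()].
#' @return a `T x (T_stim + T_self + 1)` numeric matrix with attribute
#'   `shape`.
#' @export
build_design <- function(x, y, shape = model_shape()) {
  T_ <- length(x)
  if (length(y) != T_) stop("build_design: x and y lengths differ")
  cs <- cumsum(x)
  xt <- cs - lag0(cs, shape$d_stim)   # box-prefiltered stimulus
  X <- matrix(0, T_, n_params(shape))
  for (tau in 0:(shape$T_stim - 1L))
    X[, tau + 1L] <- lag0(xt, tau * shape$d_stim)
  for (tau in seq_len(shape$T_self))
    X[, shape$T_stim + tau] <- lag0(y, tau)
  X[, ncol(X)] <- 1
  attr(X, "shape") <- shape
  X
}

# Ceiling on the linear predictor inside exp() during optimization; avoids
# overflow while leaving the optimum untouched in non-pathological fits
# (evaluations that hit it are flagged).
ETA_CEILING <- 30

#' Poisson GLM log-likelihood, gradient and Hessian
#'
#' Computes `sum_t [ y(t) * eta(t) - exp(eta(t)) - log(y(t)!) ]` where
#' `eta = X %*% beta` is the linear predictor. On request the gradient
#' `X' (y - exp(eta))` and Hessian `-X' diag(exp(eta)) X` are attached as
#' attributes `gradient` and `hessian`.
#'
#' @param beta parameter vector (or [glm_params()]).
#' @param X design matrix from [build_design()].
#' @param y spike counts.
#' @param gradient,hessian logical; attach derivatives.
#' @param eta_max ceiling on the linear predictor inside `exp` (default
#'   `Inf`: unclamped). Evaluations that clamp carry attribute
#'   `clamped = TRUE`.
#' @return the log-likelihood, with optional attributes.
#' @export
poisson_loglik <- function(beta, X, y, gradient = FALSE, hessian = FALSE,
                           eta_max = Inf) {
  if (inherits(beta, "glm_params")) beta <- as.vector(beta)
  eta <- drop(X %*% beta)
  clamped <- any(eta > eta_max)
  eta_c <- if (clamped) pmin(eta, eta_max) else eta
  mu <- exp(eta_c)
  ll <- sum(y * eta_c - mu - lgamma(y + 1))
  out <- ll
  if (gradient) attr(out, "gradient") <- drop(crossprod(X, y - mu))
  if (hessian) attr(out, "hessian") <- -crossprod(X * mu, X)
  attr(out, "clamped") <- clamped
  out
}

# Maximize  ll(beta)/T_norm - 0.5 * sum(penalty * beta^2)  by damped Newton.
# `penalty` is a per-coefficient ridge weight (0 for the offset); the offset
# (last coordinate) is box-constrained to `beta0_bounds` so that the problem
# stays well-posed for zero-spike neurons. Returns the flat parameter vector
# with convergence diagnostics as attributes.
newton_poisson <- function(X, y, penalty, T_norm = 1,
                           init = NULL, prior_mean = NULL,
                           beta0_bounds = c(-30, 30),
                           tol = 1e-6, max_iter = 500L,
                           eta_max = ETA_CEILING) {
  p <- ncol(X)
  if (is.null(prior_mean)) prior_mean <- numeric(p)
  beta <- if (is.null(init)) {
    b <- numeric(p)
    b[p] <- min(max(log(max(mean(y), 1e-8)), beta0_bounds[1]), beta0_bounds[2])
    b
  } else pmin(pmax(init, c(rep(-Inf, p - 1L), beta0_bounds[1])),
              c(rep(Inf, p - 1L), beta0_bounds[2]))

  obj <- function(b) {
    as.numeric(poisson_loglik(b, X, y, eta_max = eta_max)) / T_norm -
      0.5 * sum(penalty * (b - prior_mean)^2)
  }
  f <- obj(beta)
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(max_iter)) {
    iters <- it
    eta <- pmin(drop(X %*% beta), eta_max)
    mu <- exp(eta)
    g <- drop(crossprod(X, y - mu)) / T_norm - penalty * (beta - prior_mean)
    # project the offset gradient at an active bound
    if (beta[p] <= beta0_bounds[1] && g[p] < 0) g[p] <- 0
    if (beta[p] >= beta0_bounds[2] && g[p] > 0) g[p] <- 0
    if (max(abs(g)) < tol) { converged <- TRUE; break }
    H <- crossprod(X * mu, X) / T_norm
    diag(H) <- diag(H) + penalty
    step <- tryCatch(solve(H, g), error = function(e) {
      solve(H + diag(1e-8 * max(diag(H)), p), g)
    })
    # backtracking line search on the concave objective
    alpha <- 1
    repeat {
      cand <- beta + alpha * step
      cand[p] <- min(max(cand[p], beta0_bounds[1]), beta0_bounds[2])
      f_cand <- obj(cand)
      if (is.finite(f_cand) && f_cand >= f - 1e-12 * abs(f)) break
      alpha <- alpha / 2
      if (alpha < 1e-12) { cand <- beta; f_cand <- f; break }
    }
    if (max(abs(cand - beta)) == 0 && max(abs(g)) >= tol) {
      # cannot make progress (numerically at the optimum)
      beta <- cand; f <- f_cand
      converged <- max(abs(g)) < 1e-3
      break
    }
    beta <- cand; f <- f_cand
  }
  if (!converged && iters >= max_iter)
    stop(sprintf(
      "newton_poisson: no convergence after %d iterations (|grad| = %.3g)",
      max_iter, max(abs(g))))
  attr(beta, "objective") <- f
  attr(beta, "iterations") <- iters
  attr(beta, "offset_at_bound") <- beta[p] %in% beta0_bounds
  beta
}

#' Ridge penalty weights for the single-cell GLM
#' @param lambda_stim,lambda_self nonnegative l2 penalties on the stimulus and
#'   self-interaction filters (the offset is never penalized).
#' @return an object of class `reg_weights`.
#' @export
reg_weights <- function(lambda_stim, lambda_self) {
  stopifnot(lambda_stim >= 0, lambda_self >= 0)
  structure(list(lambda_stim = lambda_stim, lambda_self = lambda_self),
            class = "reg_weights")
}

penalty_vector <- function(reg, shape) {
  c(rep(reg$lambda_stim, shape$T_stim), rep(reg$lambda_self, shape$T_self), 0)
}

#' Fit one neuron's penalized Poisson GLM (MAP estimate)
#'
#' Maximizes the per-bin-normalized log-likelihood minus l2 penalties on the
#' stimulus and self-interaction filters (the offset is unpenalized but
#' box-constrained to `[-30, 30]` so zero-spike neurons stay well-posed). The
#' objective is concave, so the optimum is unique; it is found by damped
#' Newton iterations with analytic gradient and Hessian.
#'
#' @param x,y stimulus and spike-count vectors.
#' @param shape a [model_shape()].
#' @param reg a [reg_weights()].
#' @param normalize_by number of bins the training log-likelihood is divided
#'   by (defaults to `length(y)`); keeps the penalties comparable across
#'   training sets of different sizes.
#' @param init optional starting vector.
#' @param tol gradient-norm convergence tolerance.
#' @param max_iter Newton iteration cap.
#' @return a [glm_params()] with attributes `objective`, `iterations`,
#'   `offset_at_bound`.
#' @export
fit_glm <- function(x, y, shape = model_shape(), reg = reg_weights(1e-4, 1e-4),
                    normalize_by = length(y), init = NULL,
                    tol = 1e-6, max_iter = 500L) {
  X <- build_design(x, y, shape)
  b <- newton_poisson(X, y, penalty_vector(reg, shape),
                      T_norm = normalize_by, init = init,
                      tol = tol, max_iter = max_iter)
  out <- params_from_vector(as.numeric(b), shape)
  attributes(out)[c("objective", "iterations", "offset_at_bound")] <-
    attributes(b)[c("objective", "iterations", "offset_at_bound")]
  class(out) <- "glm_params"
  out
}

# Row indices of partition l for a neuron record.
partition_rows <- function(rec, l) {
  seq.int(rec$partitions[l, "start"], rec$partitions[l, "end"])
}

#' Select ridge penalties by cross-validated log-likelihood
#'
#' For a log-spaced grid of `(lambda_stim, lambda_self)` pairs, fits each
#' neuron on all partitions but one and scores the held-out partition,
#' accumulating the per-bin-normalized held-out log-likelihood over all
#' neurons and folds. One shared pair is selected for the whole dataset (the
#' cross-validation score sums over neurons before maximizing); ties are
#' broken toward larger penalties.
#'
#' @param ds a [spike_dataset()]; every neuron needs >= 2 partitions.
#' @param shape a [model_shape()].
#' @param grid_size points per axis of the log-spaced grid.
#' @param lambda_range range of both penalty grids.
#' @return the selected [reg_weights()], with the full score table attached as
#'   attribute `scores` (columns lambda_stim, lambda_self, cvll).
#' @export
select_lambdas <- function(ds, shape = model_shape(), grid_size = 8L,
                           lambda_range = c(1e-7, 1)) {
  validate_dataset(ds)
  L_per <- vapply(ds$neurons, function(r) nrow(r$partitions), integer(1))
  if (any(L_per < 2L))
    stop("select_lambdas: every neuron needs at least 2 partitions")
  grid <- 10^seq(log10(lambda_range[1]), log10(lambda_range[2]),
                 length.out = grid_size)
  N <- length(ds$neurons)
  designs <- lapply(ds$neurons, function(r)
    build_design(r$stimulus, r$spikes, shape))
  scores <- expand.grid(lambda_stim = grid, lambda_self = grid)
  scores$cvll <- NA_real_
  best <- list(v = -Inf, reg = NULL)
  for (g in seq_len(nrow(scores))) {
    reg <- reg_weights(scores$lambda_stim[g], scores$lambda_self[g])
    v <- 0
    ok <- TRUE
    for (i in seq_len(N)) {
      rec <- ds$neurons[[i]]
      X <- designs[[i]]; y <- rec$spikes; T_i <- length(y)
      warm <- NULL
      for (l in seq_len(nrow(rec$partitions))) {
        held <- partition_rows(rec, l)
        tr <- setdiff(seq_len(T_i), held)
        b <- tryCatch(
          newton_poisson(X[tr, , drop = FALSE], y[tr],
                         penalty_vector(reg, shape), T_norm = length(tr),
                         init = warm),
          error = function(e) NULL)
        if (is.null(b)) { ok <- FALSE; break }
        warm <- as.numeric(b)
        v <- v + as.numeric(
          poisson_loglik(as.numeric(b), X[held, , drop = FALSE], y[held],
                         eta_max = 700)) / (N * T_i)
      }
      if (!ok) break
    }
    if (!ok)
      warning(sprintf("select_lambdas: fit failed at lambda_stim = %g, lambda_self = %g; point scored -Inf",
                      reg$lambda_stim, reg$lambda_self))
    scores$cvll[g] <- if (ok) v else -Inf
    # grid is iterated in increasing lambda order; >= breaks ties upward
    if (ok && v >= best$v) best <- list(v = v, reg = reg)
  }
  if (is.null(best$reg)) stop("select_lambdas: all grid points failed")
  attr(best$reg, "scores") <- scores
  best$reg
}
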