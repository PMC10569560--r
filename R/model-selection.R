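# Model selection: BIC heuristic over K (and lambda_stim for the
# simultaneous method), and a basic held-out-neuron cross-validation score.

#' Degrees of freedom of a cluster model
#'
#' `K - 1` free mixture weights plus `K * T_self` means plus `K * T_self`
#' diagonal variances: `K * (2 * T_self + 1) - 1`.
#'
#' @param K number of clusters.
#' @param T_self self-interaction filter length.
#' @return integer degrees of freedom.
#' @export
dof <- function(K, T_self) {
  stopifnot(K >= 1, T_self >= 1)
  as.integer(K * (2L * T_self + 1L) - 1L)
}

#' BIC heuristic for a fitted cluster model
#'
#' `sum_i LL_i - dof/2 * log(N)`, penalizing by the number of neurons (not
#' time bins); larger is better. `LL_i` is the method's per-neuron score: the
#' approximate marginal log-likelihood `log sum_k Z_{i,k}` for the
#' simultaneous method, the GMM mixture log-density for the sequential one.
#'
#' @param ll_per_neuron numeric vector of per-neuron scores.
#' @param K number of clusters.
#' @param T_self self-filter length.
#' @return scalar BIC (larger is better).
#' @export
bic <- function(ll_per_neuron, K, T_self) {
  N <- length(ll_per_neuron)
  stopifnot(N >= 1)
  sum(ll_per_neuron) - dof(K, T_self) / 2 * log(N)
}

#' Grid search over K (and lambda_stim) by BIC
#'
#' Fits the chosen method at every grid point with its full restart protocol
#' and scores each fit by [bic()]. For the sequential method the ridge
#' penalties are selected once (or passed via `reg`) and the grid is over `K`
#' only; for the simultaneous method the grid is `K x lambda_stim`. Ties break
#' to the smallest `K`, then the largest `lambda_stim`. A failed fit scores
#' `-Inf` and selection proceeds.
#'
#' @param ds a [spike_dataset()].
#' @param shape a [model_shape()].
#' @param K_grid integer vector of cluster counts.
#' @param lambda_grid `lambda_stim` grid for the simultaneous method (default
#'   log-spaced over `[1e-7, 1]`).
#' @param method `"sequential"` or `"simultaneous"`.
#' @param seed master seed.
#' @param ... passed to [run_sequential()] / [fit_simultaneous()] (e.g.
#'   `n_restarts`, `reg`).
#' @return a `selection_report`: data frame `grid` (K, lambda_stim, ll_sum,
#'   dof, bic), the `chosen` row, and the fit at the chosen point.
#' @export
select_model <- function(ds, shape = model_shape(), K_grid,
                         lambda_grid = 10^seq(-7, 0, length.out = 4L),
                         method = c("sequential", "simultaneous"),
                         seed = 1L, ...) {
  method <- match.arg(method)
  stopifnot(length(K_grid) >= 1)
  if (method == "sequential") lambda_grid <- NA_real_
  grid <- expand.grid(K = as.integer(K_grid), lambda_stim = lambda_grid)
  # order so that the strict-> tie rule (smallest K, then largest lambda)
  # falls out of a ">" comparison scan
  grid <- grid[order(grid$K, -grid$lambda_stim), , drop = FALSE]
  grid$ll_sum <- NA_real_; grid$dof <- dof(grid$K, shape$T_self)
  grid$bic <- NA_real_
  fits <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    fit <- tryCatch({
      if (method == "sequential")
        run_sequential(ds, shape, K = grid$K[g],
                       seed = derive_seed(seed, g), ...)
      else
        fit_simultaneous(ds, shape, K = grid$K[g],
                         lambda_stim = grid$lambda_stim[g],
                         seed = derive_seed(seed, g), ...)
    }, error = function(e) {
      warning(sprintf("select_model: fit failed at K=%d (%s)",
                      grid$K[g], conditionMessage(e)))
      NULL
    })
    fits[[g]] <- fit
    if (!is.null(fit)) {
      grid$ll_sum[g] <- sum(fit$ll_per_neuron)
      grid$bic[g] <- bic(fit$ll_per_neuron, grid$K[g], shape$T_self)
    } else grid$bic[g] <- grid$ll_sum[g] <- -Inf
  }
  chosen <- which.max(grid$bic)   # first max: smallest K, largest lambda
  structure(list(grid = grid, chosen = grid[chosen, , drop = FALSE],
                 fit = fits[[chosen]], method = method),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("<selection_report: %s method>\n", x$method))
  print(x$grid, row.names = FALSE)
  cat(sprintf("chosen: K = %d%s\n", x$chosen$K,
              if (is.na(x$chosen$lambda_stim)) "" else
                sprintf(", lambda_stim = %g", x$chosen$lambda_stim)))
  invisible(x)
}

#' Held-out-neuron cross-validation score
#'
#' Scores neurons that were not used to fit the cluster model. For the
#' simultaneous method, runs one [e_step()] for the held-out neurons against
#' the fitted model and returns the mean of `log sum_k Z_{i,k}`. For the
#' sequential method, fits each held-out neuron's GLM individually (with the
#' penalties stored in the fit) and returns the mean GMM log-density of the
#' fitted self filters.
#'
#' @param train the training [spike_dataset()] `fitted` was produced on.
#' @param heldout a disjoint [spike_dataset()] of evaluation neurons.
#' @param fitted a `fit_result`.
#' @return scalar mean held-out score (larger is better).
#' @export
cvll_heldout <- function(train, heldout, fitted) {
  if (length(heldout$neurons) < 1L) stop("cvll_heldout: empty held-out set")
  shape <- fitted$shape
  if (fitted$method == "simultaneous") {
    post <- e_step(heldout, fitted$omega, shape)
    mean(apply(post$logZ, 1L, logsumexp))
  } else {
    betas <- lapply(heldout$neurons, function(rec)
      fit_glm(rec$stimulus, rec$spikes, shape, fitted$reg))
    mean(gmm_loglik(stack_self(betas), fitted$omega))
  }
}
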