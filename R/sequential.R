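# Sequential method: fit every neuron's GLM independently, then cluster the
# fitted self-interaction filters with a diagonal-covariance GMM.

# Permutation that orders clusters by descending sum of the self-filter mean;
# the convention used for reporting both methods' final models.
cluster_order <- function(model) {
  order(rowSums(model$mu_self), decreasing = TRUE)
}

permute_cluster_model <- function(model, perm) {
  cluster_model(model$pi[perm], model$mu_self[perm, , drop = FALSE],
                model$sigma_self[perm, , drop = FALSE],
                lambda_stim = model$lambda_stim, loglik = model$loglik)
}

new_fit_result <- function(method, omega, labels, betas, ll_per_neuron,
                           shape, ...) {
  structure(c(list(method = method, omega = omega, labels = labels,
                   betas = betas, ll_per_neuron = ll_per_neuron,
                   shape = shape), list(...)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result: %s method> N = %d, K = %d, sum LL_i = %.4f\n",
              x$method, length(x$labels), x$omega$K, sum(x$ll_per_neuron)))
  cat("cluster sizes:", tabulate(x$labels, x$omega$K), "\n")
  invisible(x)
}

# Matrix of fitted self filters from a list of glm_params.
stack_self <- function(betas) t(vapply(betas, function(b) b$beta_self,
                                       numeric(length(betas[[1]]$beta_self))))

#' Sequential cell-type discovery
#'
#' Step 1 fits each neuron's penalized Poisson GLM independently, with ridge
#' penalties selected by cross-validated log-likelihood (shared across all
#' neurons) unless `reg` is supplied. Step 2 fits a diagonal-covariance GMM to
#' the fitted self-interaction filters and assigns each neuron to its
#' maximum-likelihood cluster. The per-neuron score used for model selection
#' is the GMM mixture log-density of the fitted filter.
#'
#' @param ds a [spike_dataset()].
#' @param shape a [model_shape()].
#' @param K number of cell types.
#' @param grid_size per-axis size of the penalty grid (used when `reg` is
#'   `NULL`).
#' @param seed master seed for the GMM restarts.
#' @param reg optional [reg_weights()] to skip penalty selection (e.g. oracle
#'   penalties in simulation studies).
#' @param n_init GMM restarts.
#' @return a `fit_result` with elements `omega` ([cluster_model()]), `labels`,
#'   `betas` (list of [glm_params()]), `ll_per_neuron`, `reg`.
#' @export
run_sequential <- function(ds, shape = model_shape(), K, grid_size = 8L,
                           seed = 1L, reg = NULL, n_init = 20L) {
  validate_dataset(ds)
  if (is.null(reg)) reg <- select_lambdas(ds, shape, grid_size)
  betas <- lapply(ds$neurons, function(rec)
    fit_glm(rec$stimulus, rec$spikes, shape, reg))
  B <- stack_self(betas)
  omega <- fit_gmm(B, K, n_init = n_init, seed = seed)
  omega <- permute_cluster_model(omega, cluster_order(omega))
  labels <- assign_types(B, omega)
  new_fit_result("sequential", omega, labels, betas,
                 ll_per_neuron = gmm_loglik(B, omega),
                 shape = shape, reg = reg, neuron_ids = neuron_ids(ds))
}
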