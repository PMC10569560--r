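# Evaluation statistics: adjusted Rand score, thresholded filter RMS, average
# negative log-likelihood, smoothed PSTHs, explained variance and its ratio,
# and cluster-vs-metadata z-scores.

#' Adjusted Rand score between two labelings
#'
#' Chance-corrected partition agreement computed from the contingency table:
#' 1 for identical partitions (up to relabeling), ~0 for independent ones.
#' Symmetric in its arguments.
#'
#' @param labels_a,labels_b equal-length label vectors (length >= 2).
#' @return scalar adjusted Rand score.
#' @export
ars <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("ars: labelings have different lengths")
  n <- length(labels_a)
  stopifnot(n >= 2)
  tab <- table(labels_a, labels_b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)   # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Root-mean-squared filter error with exclusion of very negative truths
#'
#' RMS over the coordinates whose true value is at least `exclude_below`.
#' Coefficients far below zero suppress spiking so strongly that their exact
#' magnitude barely affects the likelihood, so they are excluded when scoring
#' self-interaction filters.
#'
#' @param true_beta,est_beta equal-length numeric vectors.
#' @param exclude_below exclusion threshold on the true value (default -4).
#' @return scalar RMS over the surviving coordinates.
#' @export
rms_filter <- function(true_beta, est_beta, exclude_below = -4) {
  if (length(true_beta) != length(est_beta))
    stop("rms_filter: length mismatch")
  keep <- true_beta >= exclude_below
  if (!any(keep)) stop("rms_filter: all coordinates excluded")
  sqrt(mean((true_beta[keep] - est_beta[keep])^2))
}

#' Average negative log-likelihood per test bin
#'
#' `-(1/T_test) log P_SC(y_test | x_test; beta)`, including the `log(y!)`
#' terms; lower is better.
#'
#' @param beta a [glm_params()].
#' @param x_test,y_test test stimulus and spike counts.
#' @param shape a [model_shape()].
#' @return scalar ANLL.
#' @export
anll <- function(beta, x_test, y_test, shape = model_shape()) {
  X <- build_design(x_test, y_test, shape)
  -as.numeric(poisson_loglik(beta, X, y_test)) / length(y_test)
}

#' Smooth a spike train into a PSTH
#'
#' Convolves the spike counts with a unit-mass Gaussian kernel (sd
#' `kernel_sd` seconds, truncated at 4 sd) using reflecting boundaries, which
#' preserves total mass near the edges.
#'
#' @param spikes spike-count vector.
#' @param bin_width bin width in seconds.
#' @param kernel_sd kernel standard deviation in seconds (default 10 ms).
#' @return an object of class `psth` with elements `values`, `kernel_sd`,
#'   `bin_width`.
#' @export
smooth_psth <- function(spikes, bin_width = 0.002, kernel_sd = 0.010) {
  stopifnot(bin_width > 0, kernel_sd > 0)
  T_ <- length(spikes)
  sd_bins <- kernel_sd / bin_width
  half <- ceiling(4 * sd_bins)
  if (half >= T_)
    stop("smooth_psth: series too short for the kernel width")
  kern <- stats::dnorm(seq(-half, half), sd = sd_bins)
  kern <- kern / sum(kern)
  padded <- c(spikes[half:1], spikes, spikes[T_:(T_ - half + 1L)])
  sm <- stats::filter(padded, kern, sides = 2L)
  structure(list(values = as.numeric(sm[(half + 1L):(half + T_)]),
                 kernel_sd = kernel_sd, bin_width = bin_width),
            class = "psth")
}

psth_values <- function(p) if (inherits(p, "psth")) p$values else as.numeric(p)

#' Explained variance between two PSTHs
#'
#' `EV = [var(p1) + var(p2) - var(p1 - p2)] / [var(p1) + var(p2)]`, with
#' population variances over time bins: 1 when the traces are identical, ~0
#' when independent, and -1 when perfectly anti-correlated.
#'
#' @param psth1,psth2 `psth` objects or numeric vectors of equal length.
#' @return scalar explained variance.
#' @export
ev <- function(psth1, psth2) {
  p1 <- psth_values(psth1); p2 <- psth_values(psth2)
  if (length(p1) != length(p2)) stop("ev: length mismatch")
  v1 <- pop_var(p1); v2 <- pop_var(p2)
  if (v1 + v2 == 0) stop("ev: both traces are constant")
  (v1 + v2 - pop_var(p1 - p2)) / (v1 + v2)
}

#' Explained-variance ratio of a fitted GLM on repeated-trial test data
#'
#' Simulates `n_sim` responses of the fitted GLM to the test stimulus,
#' averages them, and smooths the average into the model PSTH; smooths each
#' recorded trial into a single-trial PSTH and averages those into the data
#' PSTH; returns
#' `sum_j EV(stPSTH_j, PSTH_M) / sum_j EV(stPSTH_j, PSTH_D)`. Near 1 when the
#' model prediction covaries with single trials as well as the trial average
#' does.
#'
#' @param beta a [glm_params()].
#' @param test_trials list of `P >= 2` spike-count vectors, one per repeated
#'   presentation of `x_test`.
#' @param x_test the repeated stimulus waveform.
#' @param shape a [model_shape()].
#' @param bin_width bin width in seconds.
#' @param n_sim number of simulated responses (default 3000).
#' @param seed integer seed for the simulations.
#' @param kernel_sd smoothing kernel sd in seconds.
#' @return scalar EV ratio, with attribute `n_capped` counting simulated bins
#'   clipped by the runaway guard.
#' @export
ev_ratio <- function(beta, test_trials, x_test, shape = model_shape(),
                     bin_width = 0.002, n_sim = 3000L, seed = 1L,
                     kernel_sd = 0.010) {
  stopifnot(length(test_trials) >= 2L)
  sim <- simulate_spikes_batch(beta, x_test, shape, n_sim = n_sim,
                               seed = seed)
  if (sim$degenerate)
    stop("ev_ratio: degenerate (runaway) simulation under the fitted model")
  psth_m <- smooth_psth(sim$mean_train, bin_width, kernel_sd)
  st <- lapply(test_trials, smooth_psth, bin_width = bin_width,
               kernel_sd = kernel_sd)
  psth_d <- rowMeans(vapply(st, psth_values, numeric(length(x_test))))
  num <- sum(vapply(st, function(s) ev(s, psth_m), numeric(1)))
  den <- sum(vapply(st, function(s) ev(s, psth_d), numeric(1)))
  out <- num / den
  attr(out, "n_capped") <- sim$n_capped
  out
}

#' Cluster-vs-metadata enrichment z-scores
#'
#' For each cluster `i` and each category `a` of a metadata attribute,
#' compares the fraction of attribute-`a` neurons falling in cluster `i`
#' (`p_i_a`) with the overall fraction (`p_i`):
#' `Z = (p_i_a - p_i) / sqrt(p_i_a (1 - p_i_a) / N_a + p_i (1 - p_i) / N)`.
#' When both binomial variance terms vanish the z-score is reported as 0 with
#' `degenerate = TRUE`.
#'
#' @param labels cluster labels.
#' @param attribute_values same-length vector of category labels (`NA`s are
#'   dropped).
#' @return data frame with columns `cluster`, `attribute`, `n_attribute`,
#'   `p_cluster`, `p_cluster_attr`, `z`, `degenerate`.
#' @export
metadata_zscore <- function(labels, attribute_values) {
  if (length(labels) != length(attribute_values))
    stop("metadata_zscore: length mismatch")
  keep <- !is.na(attribute_values)
  labels <- labels[keep]; attribute_values <- as.character(attribute_values[keep])
  N <- length(labels)
  if (N == 0L) stop("metadata_zscore: no labeled neurons")
  clusters <- sort(unique(labels))
  attrs <- sort(unique(attribute_values))
  rows <- list()
  for (a in attrs) {
    in_a <- attribute_values == a
    N_a <- sum(in_a)
    if (N_a == 0L) { warning("attribute '", a, "' has no neurons"); next }
    for (cl in clusters) {
      p_i <- mean(labels == cl)
      p_ia <- mean(labels[in_a] == cl)
      v <- p_ia * (1 - p_ia) / N_a + p_i * (1 - p_i) / N
      degen <- v == 0
      z <- if (degen) 0 else (p_ia - p_i) / sqrt(v)
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cl, attribute = a, n_attribute = N_a, p_cluster = p_i,
        p_cluster_attr = p_ia, z = z, degenerate = degen)
    }
  }
  do.call(rbind, rows)
}
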