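# Small fixtures built in code; everything is deterministic given the seeds.

# A tiny hand-assembled dataset (not simulated from the GLM).
tiny_dataset <- function(N = 3L, T_ = 100L, L = 2L, seed = 7L,
                         metadata = TRUE) {
  withr::with_seed(seed, {
    neurons <- lapply(seq_len(N), function(i) {
      x <- rnorm(T_)
      y <- rpois(T_, 0.2)
      parts <- cbind(start = seq(1L, T_, by = T_ %/% L)[seq_len(L)],
                     end = c(seq(T_ %/% L, T_, by = T_ %/% L)[seq_len(L - 1L)],
                             T_))
      md <- if (metadata)
        c(cre_line = sample(c("Pvalb", "Sst"), 1L),
          layer = sample(c("4", "5"), 1L)) else character()
      neuron_record(sprintf("n%02d", i), x, y, partitions = parts,
                    metadata = md)
    })
    spike_dataset(neurons, name = "tiny")
  })
}

# A small simulated dataset with known ground truth; cached per options so
# several test files can share one simulation.
.sim_cache <- new.env(parent = emptyenv())
small_sim <- function(K = 3L, n_per_cluster = 6L, sigma = 0.01, T_ = 1500L,
                      n_trials = 2L, seed = 42L) {
  key <- paste(K, n_per_cluster, sigma, T_, n_trials, seed, sep = "_")
  if (is.null(.sim_cache[[key]])) {
    cfg <- simulation_config(K = K, n_per_cluster = n_per_cluster,
                             sigma = sigma, T_ = T_, n_trials = n_trials,
                             seed = seed)
    .sim_cache[[key]] <- c(make_dataset(cfg), list(cfg = cfg))
  }
  .sim_cache[[key]]
}

expect_equal_params <- function(a, b, tolerance = 1e-8) {
  expect_equal(as.vector(a), as.vector(b), tolerance = tolerance)
}
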