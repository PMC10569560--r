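# Evaluation statistics: ARS, thresholded RMS, ANLL, PSTH smoothing,
# explained variance, EV ratio, and metadata z-scores.

test_that("ars: identity, relabeling invariance, symmetry", {
  a <- c(1, 1, 2, 2, 3, 3)
  expect_identical(ars(a, a), 1)
  expect_identical(ars(a, c(7, 7, 5, 5, 9, 9)), 1)  # renamed labels
  withr::with_seed(1, {
    u <- sample(1:3, 30, replace = TRUE)
    v <- sample(1:4, 30, replace = TRUE)
  })
  expect_identical(ars(u, v), ars(v, u))
  expect_error(ars(1:3, 1:4), "lengths")
})

test_that("ars matches the contingency-table formula and a library oracle", {
  # hand case: [1,1,2,2] vs [1,2,1,2]; all pair counts differ
  a <- c(1, 1, 2, 2); b <- c(1, 2, 1, 2)
  # direct computation: sum_ij C(n_ij,2) = 0, sum_a = sum_b = 2, C(4,2) = 6
  expected <- (0 - 2 * 2 / 6) / ((2 + 2) / 2 - 2 * 2 / 6)
  expect_equal(ars(a, b), expected)
  skip_if_not_installed("mclust")
  withr::with_seed(2, {
    for (rep in 1:20) {
      u <- sample(1:4, 40, replace = TRUE)
      v <- ifelse(runif(40) < 0.6, u, sample(1:4, 40, replace = TRUE))
      expect_equal(ars(u, v), mclust::adjustedRandIndex(u, v),
                   tolerance = 1e-12)
    }
  })
})

test_that("rms_filter excludes strongly negative true coefficients", {
  expect_identical(rms_filter(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_identical(rms_filter(c(0, -5), c(1, -6)), 1)
  withr::with_seed(3, {
    tr <- rnorm(30); est <- tr + rnorm(30, sd = 0.3)
    tr[c(4, 9)] <- -7
  })
  keep <- tr >= -4
  expect_equal(rms_filter(tr, est), sqrt(mean((tr - est)[keep]^2)))
  expect_error(rms_filter(c(-5, -6), c(0, 0)), "excluded")
})

test_that("anll is the negative per-bin log-likelihood, minimized at the MLE", {
  shape <- model_shape(3L, 3L, 2L)
  x <- rnorm(40)
  beta0 <- glm_params(rep(0, 3), rep(0, 3), 0)
  expect_equal(anll(beta0, x, rep(0, 40), shape), 1)  # Poisson(0; 1) NLL
  withr::with_seed(4, {
    xs <- rnorm(600); ys <- rpois(600, 0.4)
  })
  b_hat <- fit_glm(xs, ys, shape, reg_weights(0, 0))
  a_hat <- anll(b_hat, xs, ys, shape)
  for (j in 1:3) {
    pert <- as.vector(b_hat)
    pert[j * 2] <- pert[j * 2] + 0.3
    expect_gt(anll(spiketypes:::params_from_vector(pert, shape), xs, ys,
                   shape), a_hat)
  }
})

test_that("smooth_psth conserves mass with a unit-mass kernel", {
  s <- rep(0, 400); s[200] <- 1
  p <- smooth_psth(s, bin_width = 0.002, kernel_sd = 0.010)
  expect_length(p$values, 400)
  expect_equal(sum(p$values), 1, tolerance = 1e-6)
  expect_equal(which.max(p$values), 200)
  expect_identical(smooth_psth(rep(0, 100), 0.002)$values, rep(0, 100))
  # mass conserved for an edge spike under the reflecting boundary
  s2 <- rep(0, 400); s2[3] <- 2
  expect_equal(sum(smooth_psth(s2, 0.002)$values), 2, tolerance = 1e-6)
})

test_that("ev: identity, anti-correlation, independence", {
  withr::with_seed(5, p <- smooth_psth(rpois(300, 0.5), 0.002))
  expect_equal(ev(p, p), 1)
  expect_equal(ev(p$values, -p$values + 2), -1, tolerance = 1e-12)
  expect_error(ev(rep(1, 10), rep(2, 10)), "constant")
  withr::with_seed(6, {
    m <- mean(replicate(300, ev(rnorm(200), rnorm(200))))
  })
  expect_lt(abs(m), 0.02)
})

test_that("ev_ratio is near 1 for the generating model, near 0 for a flat one", {
  shape <- model_shape()
  truth <- glm_params(default_stim_filter(), default_cluster_means(3)[1, ], -5)
  x <- gen_pink_noise(1500L, seed = 41)
  trials <- lapply(1:12, function(j)
    as.numeric(simulate_spikes(truth, x, shape, seed = 100 + j)))
  r_true <- ev_ratio(truth, trials, x, shape, n_sim = 400L, seed = 9L)
  expect_gt(r_true, 0.85)
  expect_lt(r_true, 1.15)
  # constant-rate model with no stimulus or history dependence
  flat <- glm_params(rep(0, 10), rep(0, 20), log(mean(unlist(trials))))
  r_flat <- ev_ratio(flat, trials, x, shape, n_sim = 400L, seed = 9L)
  expect_lt(abs(r_flat), 0.2)
  expect_lt(r_flat, r_true)
})

test_that("metadata z-scores match the printed formula and its symmetries", {
  # balanced attribute: zero numerator
  labels <- rep(1:2, 10)
  attrs <- rep(c("a", "b"), each = 10)
  z <- metadata_zscore(labels, attrs)
  expect_true(all(abs(z$z) < 1e-12))
  # hand evaluation: N = 100, N_a = 20, p_i = 0.5, p_i_a = 0.75
  labels2 <- c(rep(1, 15), rep(2, 5), rep(1, 35), rep(2, 45))
  attrs2 <- c(rep("a", 20), rep("b", 80))
  z2 <- metadata_zscore(labels2, attrs2)
  row <- z2[z2$cluster == 1 & z2$attribute == "a", ]
  expect_equal(row$z,
               (0.75 - 0.5) / sqrt(0.75 * 0.25 / 20 + 0.5 * 0.5 / 100))
  # swapping in/out counts flips the numerator's sign
  row2 <- z2[z2$cluster == 2 & z2$attribute == "a", ]
  expect_equal(row2$z, -row$z)
})

test_that("degenerate z-scores are flagged, not NaN", {
  z <- metadata_zscore(rep(1, 10), rep(c("a", "b"), 5))
  expect_true(all(z$degenerate))
  expect_true(all(z$z == 0))
})
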