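# spiketypes

Discovering **functional cell types** from spike-train recordings, and using
them to improve single-neuron response models.

## The problem

Electrophysiologists record many neurons responding to injected currents and
want two things at once: a predictive model of each neuron's spiking, and a
grouping of neurons into types that share response properties. The common
*sequential* recipe fits each neuron separately and then clusters the fitted
parameters — but single-neuron estimates are noisy, and the clustering
inherits all of that noise. `spiketypes` also implements a *simultaneous*
(hierarchical) alternative in which cell types and single-cell parameters are
estimated together, so each neuron's estimate borrows strength from every
other neuron of its type.

## The model

Spike counts in 2 ms bins follow a Poisson GLM:

    y_i(t) ~ Poisson( exp[ beta_stim . x~(t-history) + beta_self . y(t-history) + beta0 ] )

with a downsampled stimulus filter `beta_stim` (10 taps, 5-bin box
prefilter = 100 ms), a spike-history *self-interaction filter* `beta_self`
(20 taps = 40 ms), and an offset. Cell types are clusters of self-interaction
filters:

* **Sequential** (`run_sequential`): per-neuron penalized MAP fits
  (cross-validated ridge penalties), then a diagonal-covariance Gaussian
  mixture on the fitted `beta_self`, best of 20 restarts.
* **Simultaneous** (`fit_simultaneous`): a mixture-of-GLMs in which
  `beta_self ~ N(mu_k, Sigma_k)` given latent type `k`, fitted by
  expectation-maximization with a per-(neuron, type) weighted-Gaussian
  (Laplace) approximation — mode, diagonal curvature, and evidence weight
  `Z_ik` — and closed-form M-step updates of the type weights, means, and
  variances.

Model selection uses a BIC heuristic over the number of types K (and the
stimulus-prior precision), `select_model`; evaluation uses the adjusted Rand
score, filter RMS with the −4 exclusion rule, per-bin negative
log-likelihood, explained-variance ratio on repeated trials, and
cluster-vs-metadata enrichment z-scores. A full synthetic-data generator
(`make_dataset`) reproduces the pink-noise simulation-study design.

## A worked example

```r
library(spiketypes)

# 60 neurons in 3 types, 2 trials x 2500 bins each (runs in ~2-3 minutes)
cfg <- simulation_config(K = 3, n_per_cluster = 20, sigma = 0.02,
                         T_ = 2500, n_trials = 2, seed = 1)
sim <- make_dataset(cfg)

fit_seq <- run_sequential(sim$dataset, K = 3,
                          reg = reg_weights(1e-5, 1e-4), seed = 1)
fit_sim <- fit_simultaneous(sim$dataset, K = 3, lambda_stim = 100,
                            n_restarts = 2, seed = 1, max_iter = 150)

c(sequential   = ars(fit_seq$labels, sim$labels),
  simultaneous = ars(fit_sim$labels, sim$labels))
#>   sequential simultaneous
#>    0.9018475    0.9495627

sapply(list(fit_seq, fit_sim), function(f)
  mean(sapply(seq_along(sim$params), function(i)
    rms_filter(sim$params[[i]]$beta_self, f$betas[[i]]$beta_self))))
#> [1] 0.596 0.192
```

The adjusted Rand score is 1 when a labeling matches the ground-truth types
exactly (up to renaming) and about 0 at chance; here the simultaneous method
labels the three simulated types more accurately than the sequential one
(0.95 vs 0.90), and — the borrowing-strength effect — its self-interaction
filter estimates are three times closer to the truth (RMS 0.19 vs 0.60 over
the identifiable coefficients), because each neuron's estimate is shrunk
toward a cluster mean pooled from the other neurons of its type.

There is also a thin command-line wrapper:

```sh
Rscript inst/cli/spiketypes.R simulate --K 3 --sigma 0.01 --seed 1 --out data/
Rscript inst/cli/spiketypes.R fit-simultaneous --data data/ --K 3 --out fit/
Rscript inst/cli/spiketypes.R help
```

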