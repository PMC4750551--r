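# sparsemix

Bayesian model-based clustering with **sparse finite Gaussian mixtures**,
for analysts who want the number of clusters, the cluster-relevant
variables and identified component-specific parameters out of a single
MCMC run — without marginal likelihoods, information criteria or
reversible-jump samplers.

## The method

A deliberately **overfitting** mixture
`f(y_i) = Σ_{k=1..K} η_k N(y_i | μ_k, Σ_k)` is fit with `K` far larger
than the expected number of clusters, under a sparse symmetric Dirichlet
prior `η ~ Dir(e0, …, e0)` whose hyperparameter `e0` is either fixed very
small or given the hyperprior `e0 ~ G(a, aK)` (prior mean `1/K`).
Small `e0` makes the posterior empty superfluous components during Gibbs
sampling. Per sweep `m` the number of non-empty components is

    K0(m) = K − #{k : Nk(m) = 0},

and the estimated number of clusters `K̂0` is the **posterior mode** of
the `K0` frequencies — the most frequent number of non-empty components
visited by the sampler.

Component means carry either the standard prior `μ_k ~ N(b0, R0)`
(data median and squared ranges) or a hierarchical **normal-gamma
shrinkage prior** `μ_k ~ N(b0, Λ R0 Λ)`, `λ_j ~ G(ν1, ν2)`, whose
per-variable scale factors `λ_j` pull component means together in
dimensions without cluster structure: implicit variable selection, read
off the posterior of `λ_j`. Covariances are unconstrained with a
hierarchical Wishart prior `Σ_k⁻¹ ~ W(c0, C0)`, `C0 ~ W(g0, G0)`.

Estimation is by data augmentation and Gibbs sampling (with a
generalized-inverse-Gaussian step for the `λ_j`, a random-walk
Metropolis step for a random `e0`, and a random permutation step).
Label switching is resolved afterwards in the **point-process
representation**: mean draws of non-empty components from sweeps with
`K0(m) = K̂0` are clustered by K-centroids cluster analysis under
cluster-specific **Mahalanobis distances**; sweeps whose cluster labels
form a permutation are relabeled, the rest are discarded, and the
discarded fraction `M0,ρ` (non-permutation rate) is reported as a
separation diagnostic.

## Worked example

Simulate the 4-component benchmark (means `±(2,−2,0,0)`, `±(2,2,0,0)`,
identity covariances, equal weights — only the first two of four
variables carry cluster structure), then fit a sparse mixture with
`K = 15` components:

```r
library(sparsemix)

truth <- mixture_preset("equal_weights")
d     <- simulate_mixture(truth, N = 1000, seed = 42)
prior <- default_priors(d, K = 15, mean_prior = "standard", e0 = "gamma")
fit   <- fit_sparse_mix(d, prior = prior,
                        opts = mcmc_options(M = 3000, burnin = 1000, seed = 42))
fit
#> Sparse finite Gaussian mixture fit (overfitting K = 15)
#>   estimated clusters K0_hat = 4 (M0 = 2879 of 3000 sweeps)
#>   non-permutation rate M0_rho = 0
#>   posterior median e0 = 0.0564
#>   partition sizes: 247, 275, 251, 227

evaluate_fit(fit, truth = truth)
#> Sparse finite mixture evaluation
#>   e0_hat (posterior median): 0.0564
#>   K0_hat = 4, M0 = 2879, M0_rho = 0
#>   MCR = 0.053
#>   MSE_mu = 0.2102
```

Eleven of the fifteen components are emptied almost immediately: the
sampler spends 96% of its sweeps at exactly 4 non-empty components, and
the posterior median of `e0` settles near 0.056 — the data asked for
strong sparsity. Every identified sweep's labels form a permutation
(`M0_rho = 0`, well-separated component posteriors), the partition
recovers the four groups of ~250 with a 5.3% misclassification rate
(the clusters overlap by construction, so a few percent is the
attainable floor), and `MSE_mu` is the summed Mahalanobis mean-squared
error of the identified component-mean draws around the true means.
Under the shrinkage prior (`mean_prior = "normalgamma"`, `e0 = 0.01`)
the same data give a smaller `MSE_mu` and posterior `λ_j` medians near
0.09 for the two cluster-relevant variables versus essentially zero for
the two homogeneous ones — `shrinkage_summary(fit$trace)` tabulates them.

Real data enter through `read_mixture_data("file.csv", label_col = …)`
or `mixture_data(as.matrix(df))`; `run_fit()` writes the full artifact
set (traces, K0 distribution, identified draws, partition, JSON report)
for a data file or preset, and `replicate_study()` runs replicated
simulation studies over a grid of (prior, K, e0) cells. Benchmark
datasets with known labels (e.g. the crabs or iris morphometric data)
are not bundled; export them to CSV and pass the label column to
reproduce the published-style tables — e.g.
`run_fit(list(data = "crabs.csv", label_col = "group", K = 15,
prior = "standard", e0 = "gamma", M = 10000, burnin = 2000, seed = 1,
outdir = "crabs-out"))`.

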