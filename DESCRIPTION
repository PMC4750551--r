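Package: sparsemix
Title: Sparse Finite Gaussian Mixtures for Model-Based Clustering
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Bayesian model-based clustering with sparse finite Gaussian
    mixtures. A deliberately overfitting mixture is combined with a sparse
    symmetric Dirichlet prior on the weights so that superfluous components
    are emptied during MCMC sampling; the number of data clusters is
    estimated by the posterior mode of the number of non-empty components.
    A hierarchical normal-gamma shrinkage prior on the component means
    performs implicit selection of cluster-relevant variables. Estimation
    uses data augmentation and Gibbs sampling with a generalized inverse
    Gaussian step for the shrinkage factors, a random-walk Metropolis step
    for the Dirichlet hyperparameter, and a random permutation step. An
    identified model is obtained by clustering the point-process
    representation of the component-mean draws with K-centroids cluster
    analysis based on cluster-specific Mahalanobis distances.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
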