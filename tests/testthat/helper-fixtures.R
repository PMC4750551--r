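# shared fixtures built in code

# small well-separated 2D dataset with known labels
make_blobs <- function(n_per = 20L, centers = rbind(c(-4, 0), c(4, 0)),
                       sd = 0.5, seed = 1L) {
  set.seed(seed)
  K <- nrow(centers)
  y <- do.call(rbind, lapply(seq_len(K), function(k)
    cbind(rnorm(n_per, centers[k, 1L], sd),
          rnorm(n_per, centers[k, 2L], sd))))
  mixture_data(y, labels = rep(seq_len(K), each = n_per))
}

# tiny deterministic trace object for identification tests: M sweeps,
# K components, r dims; non-empty components and their means supplied
# per sweep
make_toy_trace <- function(mu_by_sweep, Nk_by_sweep, eta_by_sweep = NULL,
                           r = ncol(mu_by_sweep[[1L]])) {
  M <- length(mu_by_sweep)
  K <- length(Nk_by_sweep[[1L]])
  mu <- array(0, c(M, K, r))
  Sigma <- array(diag(r), c(r, r, K, M))
  eta <- matrix(1 / K, M, K)
  Nk <- matrix(0L, M, K)
  for (m in seq_len(M)) {
    mu[m, , ] <- mu_by_sweep[[m]]
    Nk[m, ] <- Nk_by_sweep[[m]]
    if (!is.null(eta_by_sweep)) eta[m, ] <- eta_by_sweep[[m]]
  }
  structure(list(mu = mu, Sigma = Sigma, eta = eta, Nk = Nk,
                 lam = NULL, e0 = rep(0.01, M),
                 K0 = apply(Nk, 1L, function(x) sum(x > 0L)),
                 S = NULL, M = M, K = K, r = r, N = sum(Nk[1L, ]),
                 mean_prior = "standard", e0_random = FALSE,
                 acceptance_rate_e0 = NA_real_),
            class = "sfm_trace")
}

# all permutations of 1..n (n small)
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

# synthetic "posterior" point process with sweep structure: M0 sweeps,
# one point per component, components drawn around given centers with
# given covariances
make_synthetic_pps <- function(centers, covs, M0 = 150L, seed = 1L) {
  set.seed(seed)
  K <- nrow(centers)
  r <- ncol(centers)
  pts <- matrix(NA_real_, K * M0, r)
  sweep_idx <- integer(K * M0)
  comp_idx <- integer(K * M0)
  pos <- 0L
  for (m in seq_len(M0)) {
    ord <- sample.int(K)   # label switching across sweeps
    for (j in seq_len(K)) {
      k <- ord[j]
      L <- chol(covs[, , k])
      pts[pos + j, ] <- centers[k, ] + drop(t(L) %*% rnorm(r))
      comp_idx[pos + j] <- j
    }
    sweep_idx[pos + seq_len(K)] <- m
    attr(pts, paste0("truth", m)) <- ord
    pos <- pos + K
  }
  structure(list(points = pts, sweep = sweep_idx, comp = comp_idx,
                 M0 = M0, K_hat = K),
            class = "point_process")
}
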