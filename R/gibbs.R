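#' MCMC run options
#'
#' @param M Number of retained sweeps.
#' @param burnin Number of discarded warm-up sweeps.
#' @param seed Integer seed; every source of randomness in a run derives
#'   from it.
#' @param mh_log_step Scale \eqn{\tau} of the log-scale random-walk proposal
#'   for the Dirichlet hyperparameter \eqn{e_0}.
#' @param store_allocations Keep the allocation vector of every retained
#'   sweep (needed for the final partition; costs `N * M` integers).
#' @param permute Apply the random permutation step after each sweep.
#' @return An object of class `mcmc_options`.
#' @export
mcmc_options <- function(M = 10000, burnin = 2000, seed = 1,
                         mh_log_step = 0.5, store_allocations = TRUE,
                         permute = TRUE) {
  stopifnot(M >= 1, burnin >= 0, mh_log_step > 0)
  structure(list(M = as.integer(M), burnin = as.integer(burnin),
                 seed = as.integer(seed), mh_log_step = mh_log_step,
                 store_allocations = isTRUE(store_allocations),
                 permute = isTRUE(permute)),
            class = "mcmc_options")
}

#' Initial chain state from a K-means classification
#'
#' The starting classification is a K-means run with `K` clusters;
#' weights are the empirical proportions, component moments come from the
#' within-cluster sample moments (ridge-regularized), shrinkage factors
#' start at 1, `b0` at the data median, `e0` at its fixed value or prior
#' mean \eqn{1/K}, and `C0` at the mean \eqn{g_0 G_0^{-1}} of its prior.
#'
#' @param data A [mixture_data()] object.
#' @param prior A [default_priors()] configuration.
#' @param seed Integer seed for the K-means initialization.
#' @return A `chain_state` list with elements `S`, `eta`, `mu`, `Sigma`,
#'   `Sigma_inv`, `C0`, `lam`, `b0`, `e0`, `Nk`.
#' @export
init_chain <- function(data, prior, seed = 1) {
  stopifnot(inherits(data, "mix_data"), inherits(prior, "mix_prior"))
  K <- prior$K
  r <- data$r
  if (K > data$N) stop("K exceeds the number of observations")
  set.seed(as.integer(seed))
  km <- tryCatch(
    stats::kmeans(data$y, centers = K, iter.max = 50L, nstart = 1L),
    error = function(e)
      stats::kmeans(data$y, centers = K, iter.max = 50L, nstart = 1L,
                    algorithm = "Lloyd"))
  S <- as.integer(km$cluster)
  Nk <- tabulate(S, nbins = K)
  overall <- stats::cov(data$y) + diag(1e-6 * data$R^2, r)
  mu <- matrix(0, K, r)
  Sigma <- array(0, c(r, r, K))
  Sigma_inv <- array(0, c(r, r, K))
  for (k in seq_len(K)) {
    rows <- data$y[S == k, , drop = FALSE]
    mu[k, ] <- if (Nk[k] > 0L) colMeans(rows) else data$med
    Sk <- if (Nk[k] > r + 1L) stats::cov(rows) + diag(1e-6 * data$R^2, r)
          else overall
    Sigma[, , k] <- Sk
    Sigma_inv[, , k] <- chol2inv(chol(Sk))
  }
  e0 <- if (prior$e0_spec$kind == "fixed") prior$e0_spec$value else 1 / K
  structure(
    list(S = S,
         eta = Nk / data$N,
         mu = mu, Sigma = Sigma, Sigma_inv = Sigma_inv,
         C0 = prior$g0 * chol2inv(chol(prior$G0)),
         lam = rep(1, r),
         b0 = data$med,
         e0 = e0,
         Nk = Nk),
    class = "chain_state")
}

#' Sample the latent allocations
#'
#' Draws each \eqn{S_i} from the categorical full conditional with
#' (non-normalized) probabilities
#' \eqn{\eta_k f_N(y_i | \mu_k, \Sigma_k)}, computed in log space with
#' per-observation max subtraction.
#'
#' @param state Current `chain_state`.
#' @param data A [mixture_data()] object.
#' @return The state with updated `S` and occupancy counts `Nk`.
#' @export
update_allocations <- function(state, data) {
  K <- length(state$eta)
  lp <- comp_logdens(data$y, state$mu, state$Sigma)
  lp <- sweep(lp, 2L, log(state$eta), "+")
  mx <- lp[, 1L]
  if (K > 1L) for (k in 2L:K) mx <- pmax(mx, lp[, k])
  if (any(!is.finite(mx)))
    stop("all component densities underflow for observation(s) ",
         paste(utils::head(which(!is.finite(mx)), 5L), collapse = ", "))
  pr <- exp(lp - mx)
  pr <- pr / rowSums(pr)
  # vectorized categorical draw: count how many cumulative cells fall
  # below the uniform for each row
  cum <- pr %*% upper.tri(diag(K), diag = TRUE)
  u <- stats::runif(nrow(pr))
  S <- as.integer(rowSums(cum < u) + 1L)
  state$S <- S
  state$Nk <- tabulate(S, nbins = K)
  state
}

#' Sample the mixture weights
#'
#' Conjugate update \eqn{\eta \sim Dir(e_0 + N_1, \ldots, e_0 + N_K)}.
#'
#' @param Nk Integer vector of occupancy counts.
#' @param e0 Dirichlet hyperparameter.
#' @return A weight vector on the K-simplex.
#' @export
update_weights <- function(Nk, e0) {
  g <- stats::rgamma(length(Nk), shape = e0 + Nk, rate = 1)
  tot <- sum(g)
  if (tot <= 0) {           # all gamma draws underflowed (tiny shapes)
    g <- rep(1, length(Nk))
    tot <- length(Nk)
  }
  g / tot
}

#' Sample the component means
#'
#' Conjugate update \eqn{\mu_k \sim N(b_k, B_k)} with
#' \eqn{B_k = (B_0^{-1} + N_k \Sigma_k^{-1})^{-1}} and
#' \eqn{b_k = B_k (B_0^{-1} b_0 + \Sigma_k^{-1} N_k \bar{y}_k)}, where
#' \eqn{B_0} is the diagonal prior covariance (squared ranges, scaled by the
#' shrinkage factors under the normal-gamma prior). For an empty component
#' this is exactly a draw from the prior \eqn{N(b_0, B_0)}.
#'
#' @param state Current `chain_state`.
#' @param data A [mixture_data()] object.
#' @param prior A [default_priors()] configuration.
#' @return The state with updated `mu`.
#' @export
update_means <- function(state, data, prior) {
  K <- prior$K
  r <- data$r
  B0_inv <- 1 / b0_var_diag(prior, state$lam)   # diagonal
  b0 <- if (prior$mean_prior == "standard") prior$b0_fixed else state$b0
  mu <- state$mu
  for (k in seq_len(K)) {
    Nk <- state$Nk[k]
    prec <- diag(B0_inv, r)
    rhs <- B0_inv * b0
    if (Nk > 0L) {
      ybar <- .colMeans(data$y[state$S == k, , drop = FALSE], Nk, r)
      prec <- prec + Nk * state$Sigma_inv[, , k]
      rhs <- rhs + state$Sigma_inv[, , k] %*% (Nk * ybar)
    }
    U <- tryCatch(chol((prec + t(prec)) / 2),
                  error = function(e)
                    stop("non-SPD posterior precision for component ", k))
    bk <- backsolve(U, backsolve(U, rhs, transpose = TRUE))
    mu[k, ] <- bk + backsolve(U, stats::rnorm(r))
  }
  state$mu <- mu
  state
}

#' Sample the component covariance matrices and the Wishart scale
#'
#' Conjugate updates under the hierarchical Wishart prior (rate
#' parameterization, \eqn{E[X] = \nu \Lambda^{-1}}):
#' \eqn{\Sigma_k^{-1} \sim W(c_0 + N_k/2,\; C_0 + \frac{1}{2}\sum_{i: S_i=k}
#' (y_i-\mu_k)(y_i-\mu_k)')} followed by
#' \eqn{C_0 \sim W(g_0 + K c_0,\; G_0 + \sum_k \Sigma_k^{-1})}.
#' An empty component draws \eqn{\Sigma_k^{-1}} from its prior
#' \eqn{W(c_0, C_0)}.
#'
#' @inheritParams update_means
#' @return The state with updated `Sigma`, `Sigma_inv` and `C0`.
#' @export
update_covariances <- function(state, data, prior) {
  K <- prior$K
  r <- data$r
  sum_prec <- matrix(0, r, r)
  for (k in seq_len(K)) {
    rate <- state$C0
    if (state$Nk[k] > 0L) {
      dev <- data$y[state$S == k, , drop = FALSE] -
        rep(state$mu[k, ], each = state$Nk[k])
      rate <- rate + 0.5 * crossprod(dev)
    }
    prec <- rwishart_rate(prior$c0 + state$Nk[k] / 2, rate)
    state$Sigma_inv[, , k] <- prec
    state$Sigma[, , k] <- chol2inv(chol(prec))
    sum_prec <- sum_prec + prec
  }
  state$C0 <- rwishart_rate(prior$g0 + K * prior$c0, prior$G0 + sum_prec)
  state
}

# One draw X ~ W(nu, Lambda) in the rate parameterization
# (density prop. to |X|^(nu-(r+1)/2) exp(-tr(Lambda X)), E[X] = nu Lambda^-1),
# mapped onto stats::rWishart via df = 2 nu, scale = (2 Lambda)^-1.
rwishart_rate <- function(nu, rate_mat) {
  r <- nrow(rate_mat)
  scale <- tryCatch(chol2inv(chol(2 * (rate_mat + t(rate_mat)) / 2)),
                    error = function(e) stop("non-SPD Wishart rate matrix"))
  stats::rWishart(1L, df = 2 * nu, Sigma = scale)[, , 1L]
}

#' Sample the shrinkage factors
#'
#' Full conditional \eqn{\lambda_j \sim GIG(a_j, b_j, p_K)} with
#' \eqn{a_j = 2\nu_2}, \eqn{b_j = \sum_k (\mu_{kj} - b_{0j})^2 / R_j^2} and
#' \eqn{p_K = \nu_1 - K/2} (normal-gamma prior only).
#'
#' @param mu `K x r` matrix of component means.
#' @param b0 Current prior mean vector.
#' @param prior A [default_priors()] configuration with
#'   `mean_prior = "normalgamma"`.
#' @param R Per-variable data ranges.
#' @return Vector of `r` positive shrinkage factors.
#' @export
update_lambda <- function(mu, b0, prior, R) {
  if (prior$mean_prior != "normalgamma")
    stop("shrinkage factors are only defined under the normal-gamma prior")
  K <- nrow(mu)
  pK <- prior$nu1 - K / 2
  aj <- 2 * prior$nu2
  vapply(seq_along(R), function(j) {
    bj <- sum((mu[, j] - b0[j])^2) / R[j]^2
    if (bj < .Machine$double.xmin && pK <= 0)
      stop("degenerate GIG full conditional in dimension ", j,
           " (b_j = 0 with p_K <= 0)")
    rgig(1L, a = aj, b = bj, p = pK)
  }, numeric(1L))
}

#' Sample the hierarchical prior mean of the component means
#'
#' Conjugate update \eqn{b_0 \sim N(B_n(M_0^{-1} m_0 + B_0^{-1}\sum_k \mu_k),
#' B_n)} with \eqn{B_n = (M_0^{-1} + K B_0^{-1})^{-1}}. Under the improper
#' default \eqn{M_0^{-1} = 0} this is
#' \eqn{N(\bar{\mu}_\cdot, B_0 / K)} around the across-component mean.
#'
#' @inheritParams update_lambda
#' @param lam Current shrinkage factors.
#' @return Updated `b0` vector.
#' @export
update_b0 <- function(mu, lam, prior) {
  if (prior$mean_prior != "normalgamma")
    stop("b0 is only random under the normal-gamma prior")
  K <- nrow(mu)
  r <- ncol(mu)
  B0_inv <- diag(1 / b0_var_diag(prior, lam), r)
  prec <- prior$M0_inv + K * B0_inv
  U <- chol((prec + t(prec)) / 2)
  rhs <- prior$M0_inv %*% prior$m0 + B0_inv %*% colSums(mu)
  bn <- backsolve(U, backsolve(U, rhs, transpose = TRUE))
  drop(bn + backsolve(U, stats::rnorm(r)))
}

#' Metropolis-Hastings step for the Dirichlet hyperparameter
#'
#' One log-scale random-walk step targeting
#' \deqn{p(e_0 | \eta) \propto p(e_0) \frac{\Gamma(K e_0)}{\Gamma(e_0)^K}
#'   \left(\prod_k \eta_k\right)^{e_0 - 1},}
#' where \eqn{p(e_0) = G(a, aK)}. The proposal is
#' \eqn{e_0' = e_0 \exp(\tau z)}, \eqn{z \sim N(0,1)}, accepted with
#' probability \eqn{\min(1, target(e_0') e_0' / (target(e_0) e_0))}
#' (the extra factor is the Jacobian of the log transform). Weights are
#' floored at the smallest positive normal double before taking logs.
#'
#' @param eta Current weight vector.
#' @param e0 Current value.
#' @param prior A [default_priors()] configuration with a gamma `e0` spec.
#' @param mh_log_step Proposal scale \eqn{\tau}.
#' @return List with elements `e0` and logical `accepted`.
#' @export
update_e0 <- function(eta, e0, prior, mh_log_step = 0.5) {
  if (prior$e0_spec$kind != "gamma")
    stop("e0 is fixed under this prior configuration")
  K <- prior$K
  sum_log_eta <- sum(log(pmax(eta, .Machine$double.xmin)))
  lt <- function(x)
    stats::dgamma(x, shape = prior$e0_spec$a, rate = prior$e0_spec$rate,
                  log = TRUE) +
      lgamma(K * x) - K * lgamma(x) + (x - 1) * sum_log_eta
  cur <- lt(e0)
  if (!is.finite(cur)) stop("non-finite e0 target at current state")
  prop <- e0 * exp(mh_log_step * stats::rnorm(1L))
  log_alpha <- lt(prop) - cur + log(prop) - log(e0)
  accepted <- is.finite(log_alpha) && log(stats::runif(1L)) < log_alpha
  list(e0 = if (accepted) prop else e0, accepted = accepted)
}

#' Randomly permute the component labels
#'
#' Applies a uniformly random permutation of \eqn{\{1,\ldots,K\}}
#' consistently to the weights, means, covariances, occupancy counts and
#' allocation values. The mixture likelihood of the state is unchanged;
#' the step only makes the sampler visit all \eqn{K!} symmetric posterior
#' modes.
#'
#' @param state Current `chain_state`.
#' @param perm Optional permutation to apply (defaults to a uniform draw).
#' @return The permuted state.
#' @export
permute_labels <- function(state, perm = NULL) {
  K <- length(state$eta)
  if (is.null(perm)) perm <- sample.int(K)
  # component perm[k] takes the slot k
  state$eta <- state$eta[perm]
  state$mu <- state$mu[perm, , drop = FALSE]
  state$Sigma <- state$Sigma[, , perm, drop = FALSE]
  state$Sigma_inv <- state$Sigma_inv[, , perm, drop = FALSE]
  state$Nk <- state$Nk[perm]
  inv <- integer(K)
  inv[perm] <- seq_len(K)
  state$S <- inv[state$S]
  state
}

#' Run the Gibbs sampler for a sparse finite Gaussian mixture
#'
#' Data augmentation and Gibbs sampling: each sweep updates, in this fixed
#' order, the allocations, the weights, the component means, the component
#' covariances and the Wishart scale `C0`, then (normal-gamma prior only)
#' the shrinkage factors and the hierarchical prior mean `b0`, then (random
#' `e0` only) the Metropolis-Hastings step for `e0`, and finally applies the
#' random permutation step. Per retained sweep the trace records the
#' component parameters, weights, occupancy counts and the number
#' \eqn{K_0^{(m)}} of non-empty components.
#'
#' The random permutations are drawn from a dedicated generator seeded from
#' `opts$seed`, so disabling the permutation step does not shift any other
#' random draw of the run.
#'
#' @param data A [mixture_data()] object.
#' @param prior A [default_priors()] configuration.
#' @param opts An [mcmc_options()] object.
#' @param fixed_S Optional integer vector of allocations; when supplied the
#'   allocation update and permutation step are skipped and the sampler
#'   draws component parameters conditional on this fixed classification
#'   (used for Bayes estimates with known allocations).
#' @return An object of class `sfm_trace`: a list with arrays `mu`
#'   (`M x K x r`), `Sigma` (`r x r x K x M`), matrices `eta`, `Nk`, `lam`,
#'   vectors `e0`, `K0`, optional allocation matrix `S` (`N x M`), and the
#'   `e0` acceptance rate.
#' @export
run_mcmc <- function(data, prior, opts = mcmc_options(), fixed_S = NULL) {
  stopifnot(inherits(data, "mix_data"), inherits(prior, "mix_prior"),
            inherits(opts, "mcmc_options"))
  K <- prior$K
  r <- data$r
  N <- data$N
  M <- opts$M
  total <- M + opts$burnin
  ng <- prior$mean_prior == "normalgamma"
  e0_random <- prior$e0_spec$kind == "gamma"
  state <- init_chain(data, prior, seed = opts$seed)
  if (!is.null(fixed_S)) {
    fixed_S <- as.integer(fixed_S)
    stopifnot(length(fixed_S) == N, all(fixed_S >= 1L), all(fixed_S <= K))
    state$S <- fixed_S
    state$Nk <- tabulate(fixed_S, nbins = K)
  }
  do_permute <- opts$permute && is.null(fixed_S)
  # permutation substream: drawn up front under a derived seed, with the
  # main stream saved and restored around it
  perms <- NULL
  if (do_permute) {
    main_rs <- .Random.seed
    set.seed((opts$seed + 777L) %% .Machine$integer.max)
    perms <- matrix(0L, total, K)
    for (m in seq_len(total)) perms[m, ] <- sample.int(K)
    assign(".Random.seed", main_rs, envir = globalenv())
  }
  tr_mu <- array(NA_real_, c(M, K, r))
  tr_Sigma <- array(NA_real_, c(r, r, K, M))
  tr_eta <- matrix(NA_real_, M, K)
  tr_Nk <- matrix(NA_integer_, M, K)
  tr_lam <- if (ng) matrix(NA_real_, M, r) else NULL
  tr_e0 <- numeric(M)
  tr_K0 <- integer(M)
  tr_S <- if (opts$store_allocations) matrix(NA_integer_, N, M) else NULL
  n_acc <- 0L
  n_try <- 0L
  for (m in seq_len(total)) {
    res <- tryCatch({
      if (is.null(fixed_S)) state <- update_allocations(state, data)
      state$eta <- update_weights(state$Nk, state$e0)
      state <- update_means(state, data, prior)
      state <- update_covariances(state, data, prior)
      if (ng) {
        state$lam <- update_lambda(state$mu, state$b0, prior, data$R)
        state$b0 <- update_b0(state$mu, state$lam, prior)
      }
      if (e0_random) {
        step <- update_e0(state$eta, state$e0, prior, opts$mh_log_step)
        state$e0 <- step$e0
        n_try <- n_try + 1L
        if (step$accepted) n_acc <- n_acc + 1L
      }
      if (do_permute) state <- permute_labels(state, perms[m, ])
      NULL
    }, error = function(e)
      stop("sweep ", m, ": ", conditionMessage(e), call. = FALSE))
    if (m > opts$burnin) {
      i <- m - opts$burnin
      tr_mu[i, , ] <- state$mu
      tr_Sigma[, , , i] <- state$Sigma
      tr_eta[i, ] <- state$eta
      tr_Nk[i, ] <- state$Nk
      if (ng) tr_lam[i, ] <- state$lam
      tr_e0[i] <- state$e0
      tr_K0[i] <- count_nonempty(state$Nk)
      if (!is.null(tr_S)) tr_S[, i] <- state$S
    }
  }
  structure(
    list(mu = tr_mu, Sigma = tr_Sigma, eta = tr_eta, Nk = tr_Nk,
         lam = tr_lam, e0 = tr_e0, K0 = tr_K0, S = tr_S,
         M = M, K = K, r = r, N = N,
         mean_prior = prior$mean_prior,
         e0_random = e0_random,
         acceptance_rate_e0 = if (n_try > 0L) n_acc / n_try else NA_real_),
    class = "sfm_trace")
}

#' @export
print.sfm_trace <- function(x, ...) {
  cat("Sparse finite mixture trace: ", x$M, " sweeps, K = ", x$K,
      ", r = ", x$r, ", N = ", x$N, "\n", sep = "")
  tab <- table(x$K0)
  cat("  K0 distribution: ",
      paste(names(tab), "->", as.integer(tab), collapse = ", "), "\n",
      sep = "")
  if (!is.na(x$acceptance_rate_e0))
    cat("  e0 acceptance rate: ", round(x$acceptance_rate_e0, 3L), "\n",
        sep = "")
  invisible(x)
}
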