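#' Benchmark mixture truths
#'
#' Returns the exact generating parameters of the benchmark simulation
#' setups: `equal_weights` and `unequal_weights` are 4-component mixtures in
#' r = 4 dimensions with means \eqn{\mu_1 = (2,-2,0,0)'},
#' \eqn{\mu_2 = -\mu_1}, \eqn{\mu_3 = (2,2,0,0)'}, \eqn{\mu_4 = -\mu_3},
#' identity covariances, and weights \eqn{(0.25,0.25,0.25,0.25)} or
#' \eqn{(0.02,0.33,0.33,0.32)}; only the first two variables carry cluster
#' structure, the last two are homogeneous. `bivariate_illustration` is the
#' 2-component bivariate setup with means \eqn{\pm(2,0)'}, identity
#' covariances and equal weights used to illustrate allocation behavior of
#' a superfluous component.
#'
#' @param name One of `"equal_weights"`, `"unequal_weights"`,
#'   `"bivariate_illustration"`.
#' @return An object of class `mixture_truth`: list with `means`
#'   (`K_true x r`), `covs` (`r x r x K_true`), `weights`.
#' @examples
#' mixture_preset("equal_weights")$means
#' @export
mixture_preset <- function(name = c("equal_weights", "unequal_weights",
                                    "bivariate_illustration")) {
  name <- match.arg(name)
  if (name == "bivariate_illustration") {
    means <- rbind(c(-2, 0), c(2, 0))
    weights <- c(0.5, 0.5)
  } else {
    mu1 <- c(2, -2, 0, 0)
    mu3 <- c(2, 2, 0, 0)
    means <- rbind(mu1, -mu1, mu3, -mu3)
    rownames(means) <- NULL
    weights <- if (name == "equal_weights") rep(0.25, 4L)
               else c(0.02, 0.33, 0.33, 0.32)
  }
  r <- ncol(means)
  structure(list(means = means,
                 covs = array(diag(r), c(r, r, nrow(means))),
                 weights = weights, name = name),
            class = "mixture_truth")
}

#' Simulate data from a Gaussian mixture truth
#'
#' Draws component labels from the weight distribution and observations
#' from the labeled Gaussian component.
#'
#' @param truth A `mixture_truth` (e.g. [mixture_preset()]).
#' @param N Number of observations.
#' @param seed Integer seed.
#' @return A [mixture_data()] object with `labels_true` set.
#' @export
simulate_mixture <- function(truth, N = 1000, seed = 1) {
  stopifnot(inherits(truth, "mixture_truth"))
  K <- nrow(truth$means)
  r <- ncol(truth$means)
  set.seed(as.integer(seed))
  labels <- sample.int(K, N, replace = TRUE, prob = truth$weights)
  y <- matrix(NA_real_, N, r)
  for (k in seq_len(K)) {
    idx <- which(labels == k)
    if (length(idx) == 0L) next
    L <- chol(truth$covs[, , k])
    z <- matrix(stats::rnorm(length(idx) * r), length(idx), r)
    y[idx, ] <- z %*% L + rep(truth$means[k, ], each = length(idx))
  }
  mixture_data(y, labels = labels)
}

#' Replicated simulation study
#'
#' For each cell of a (prior, K, e0) grid and each replicate: simulate a
#' dataset from the preset, run the full pipeline (sampler, posterior-mode
#' estimate of the number of non-empty components, point-process
#' identification, evaluation), and average the summary columns over
#' replicates. Per-replicate seeds are derived deterministically from the
#' master seed.
#'
#' @param preset_name Passed to [mixture_preset()].
#' @param grid Data frame with columns `prior` (`"standard"` /
#'   `"normalgamma"`), `K` (integer) and `e0` (positive fixed value, or
#'   `NA` for the gamma hyperprior with `a = 10`).
#' @param replicates Number of simulated datasets per cell.
#' @param opts [mcmc_options()] used for every run (its seed field is
#'   overridden per replicate).
#' @param N Observations per simulated dataset.
#' @param master_seed Master seed from which all replicate seeds derive.
#' @return An object of class `study_result`: a data frame with one row per
#'   cell (averages over replicates) plus a `replicates` attribute holding
#'   the per-replicate rows.
#' @export
replicate_study <- function(preset_name, grid, replicates = 3L,
                            opts = mcmc_options(M = 3000, burnin = 1000),
                            N = 1000, master_seed = 1L) {
  stopifnot(is.data.frame(grid),
            all(c("prior", "K", "e0") %in% names(grid)))
  truth <- mixture_preset(preset_name)
  rows <- list()
  for (cell in seq_len(nrow(grid))) {
    for (rep_i in seq_len(replicates)) {
      seed <- derive_seed(master_seed, cell, rep_i)
      row <- tryCatch({
        dat <- simulate_mixture(truth, N = N, seed = seed)
        prior <- if (is.na(grid$e0[cell]))
          default_priors(dat, K = grid$K[cell],
                         mean_prior = grid$prior[cell], e0 = "gamma")
        else
          default_priors(dat, K = grid$K[cell],
                         mean_prior = grid$prior[cell], e0 = grid$e0[cell])
        run_opts <- opts
        run_opts$seed <- seed
        fit <- fit_sparse_mix(dat, prior = prior, opts = run_opts)
        ev <- evaluate_fit(fit, truth = truth)
        data.frame(cell = cell, replicate = rep_i,
                   prior = grid$prior[cell], K = grid$K[cell],
                   e0_fixed = grid$e0[cell],
                   e0_hat = ev$e0_hat, K_hat = ev$K_hat, M0 = ev$M0,
                   M0_rho = ev$M0_rho, MCR = ev$MCR, MSE_mu = ev$MSE_mu,
                   failed = FALSE)
      }, error = function(e) {
        warning("cell ", cell, " replicate ", rep_i, " failed: ",
                conditionMessage(e))
        data.frame(cell = cell, replicate = rep_i,
                   prior = grid$prior[cell], K = grid$K[cell],
                   e0_fixed = grid$e0[cell],
                   e0_hat = NA_real_, K_hat = NA_integer_, M0 = NA_integer_,
                   M0_rho = NA_real_, MCR = NA_real_, MSE_mu = NA_real_,
                   failed = TRUE)
      })
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (length(rows) == 0L) {
    out <- data.frame(prior = character(0L), K = integer(0L),
                      e0_fixed = numeric(0L), e0_hat = numeric(0L),
                      K_hat = integer(0L), K_hat_agree = integer(0L),
                      M0 = numeric(0L), M0_rho = numeric(0L),
                      MCR = numeric(0L), MSE_mu = numeric(0L),
                      replicates = integer(0L), failed = integer(0L))
    class(out) <- c("study_result", class(out))
    return(out)
  }
  per_rep <- do.call(rbind, rows)
  cells <- lapply(split(per_rep, per_rep$cell), function(d) {
    kh <- d$K_hat[!is.na(d$K_hat)]
    mode_kh <- if (length(kh)) {
      tab <- table(kh)
      as.integer(names(tab)[which.max(tab)])
    } else NA_integer_
    data.frame(
      prior = d$prior[1L], K = d$K[1L], e0_fixed = d$e0_fixed[1L],
      e0_hat = mean(d$e0_hat, na.rm = TRUE),
      K_hat = mode_kh,
      K_hat_agree = sum(kh == mode_kh),
      M0 = mean(d$M0, na.rm = TRUE),
      M0_rho = mean(d$M0_rho, na.rm = TRUE),
      MCR = mean(d$MCR, na.rm = TRUE),
      MSE_mu = mean(d$MSE_mu, na.rm = TRUE),
      replicates = nrow(d), failed = sum(d$failed))
  })
  out <- do.call(rbind, cells)
  rownames(out) <- NULL
  attr(out, "replicates") <- per_rep
  class(out) <- c("study_result", class(out))
  out
}

# deterministic per-replicate seed below 2^31
derive_seed <- function(master, cell, rep_i) {
  as.integer((as.numeric(master) * 7919 + cell * 104729 + rep_i * 1299709)
             %% 2147483647)
}
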