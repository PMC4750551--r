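#' Misclassification rate under optimal label matching
#'
#' The fraction of misclassified observations, minimized over injective
#' matchings of estimated to true labels. Computed on the confusion matrix
#' (padded with zero rows/columns when the label counts differ) by solving
#' the optimal assignment problem, so any relabeling of either argument
#' leaves the value unchanged.
#'
#' @param estimated Integer vector of estimated labels.
#' @param truth Integer vector of true labels, same length.
#' @return A fraction in `[0, 1]`.
#' @examples
#' misclassification_rate(c(1, 1, 2, 2), c(2, 2, 1, 1)) # 0
#' @export
misclassification_rate <- function(estimated, truth) {
  stopifnot(length(estimated) == length(truth))
  match_idx <- optimal_label_matching(estimated, truth)
  N <- length(truth)
  conf <- confusion_matrix(estimated, truth)
  matched <- sum(conf[cbind(seq_len(nrow(conf)), match_idx)])
  1 - matched / N
}

# confusion matrix over the union label sets, padded square
confusion_matrix <- function(estimated, truth) {
  est_lev <- sort(unique(estimated))
  tru_lev <- sort(unique(truth))
  conf <- table(factor(estimated, levels = est_lev),
                factor(truth, levels = tru_lev))
  conf <- unclass(conf)
  n <- max(dim(conf))
  out <- matrix(0, n, n)
  out[seq_len(nrow(conf)), seq_len(ncol(conf))] <- conf
  rownames(out) <- c(est_lev, rep(NA, n - length(est_lev)))
  colnames(out) <- c(tru_lev, rep(NA, n - length(tru_lev)))
  out
}

# column (true label position, possibly a zero-padding column) optimally
# assigned to each estimated label position; maximizes the matched count
optimal_label_matching <- function(estimated, truth) {
  conf <- confusion_matrix(estimated, truth)
  solve_assignment(max(conf) - conf)
}

#' Mahalanobis mean-squared error of identified component-mean draws
#'
#' \deqn{MSE_\mu = \sum_{k=1}^{\hat{K}_0} \frac{1}{\tilde{M}_0}
#'   \sum_{m=1}^{\tilde{M}_0} (\mu_k^{(m)} - \mu_k^{true})'
#'   (\Sigma_k^{true})^{-1} (\mu_k^{(m)} - \mu_k^{true}),}
#' the per-component average squared Mahalanobis deviation of the
#' identified mean draws from the true means, summed over components.
#' The draws must already be relabeled and matched to the truth (same
#' optimal matching as the misclassification rate).
#'
#' @param mu_draws `M_tilde x K x r` array of identified mean draws aligned
#'   with the truth.
#' @param mu_true `K x r` matrix of true component means.
#' @param Sigma_true `r x r x K` array of true component covariances.
#' @return Non-negative scalar.
#' @export
mse_mu <- function(mu_draws, mu_true, Sigma_true) {
  stopifnot(length(dim(mu_draws)) == 3L)
  M_tilde <- dim(mu_draws)[1L]
  K <- dim(mu_draws)[2L]
  r <- dim(mu_draws)[3L]
  if (M_tilde == 0L) stop("no identified draws")
  stopifnot(nrow(mu_true) == K, ncol(mu_true) == r)
  total <- 0
  for (k in seq_len(K)) {
    dev <- matrix(mu_draws[, k, ], M_tilde, r) -
      rep(mu_true[k, ], each = M_tilde)
    L <- chol(Sigma_true[, , k])
    z <- backsolve(L, t(dev), transpose = TRUE)
    total <- total + mean(.colSums(z * z, r, M_tilde))
  }
  total
}

#' Posterior summary of the shrinkage factors
#'
#' Per-variable quantiles (2.5, 25, 50, 75, 97.5%) of the \eqn{\lambda_j}
#' draws, plus an ordering of the variables by median shrinkage factor
#' (descending: most cluster-relevant first). A small posterior
#' \eqn{\lambda_j} flags a homogeneous variable whose component means are
#' pulled together.
#'
#' @param lambda_draws `M x r` matrix of shrinkage-factor draws, or an
#'   [run_mcmc()] trace from a normal-gamma run.
#' @return List with `quantiles` (`5 x r`) and `relevance_order`.
#' @export
shrinkage_summary <- function(lambda_draws) {
  if (inherits(lambda_draws, "sfm_trace")) {
    if (is.null(lambda_draws$lam))
      stop("no shrinkage factors: trace comes from a standard-prior run")
    lambda_draws <- lambda_draws$lam
  }
  lambda_draws <- as.matrix(lambda_draws)
  q <- apply(lambda_draws, 2L, stats::quantile,
             probs = c(0.025, 0.25, 0.5, 0.75, 0.975))
  colnames(q) <- paste0("var", seq_len(ncol(lambda_draws)))
  list(quantiles = q,
       relevance_order = order(q["50%", ], decreasing = TRUE))
}

#' Per-sweep allocation probabilities of one observation
#'
#' For each retained sweep, the normalized vector
#' \eqn{\eta_k f_N(y_i | \mu_k, \Sigma_k)}: the conditional probability of
#' allocating observation `i` to each component given that sweep's
#' parameters. Box plots of these probabilities for a superfluous component
#' show how much mass an empty component attracts under a given mean prior.
#'
#' @param trace An [run_mcmc()] trace.
#' @param data The [mixture_data()] the trace was fit to.
#' @param obs_index Index of the observation.
#' @return `M x K` matrix of probabilities; rows sum to 1.
#' @export
allocation_probability_trace <- function(trace, data, obs_index) {
  stopifnot(inherits(trace, "sfm_trace"),
            obs_index >= 1L, obs_index <= data$N)
  yi <- data$y[obs_index, , drop = FALSE]
  out <- matrix(NA_real_, trace$M, trace$K)
  for (m in seq_len(trace$M)) {
    lp <- log(trace$eta[m, ]) +
      comp_logdens(yi, matrix(trace$mu[m, , ], trace$K, trace$r),
                   trace$Sigma[, , , m])[1L, ]
    lp <- lp - max(lp)
    p <- exp(lp)
    out[m, ] <- p / sum(p)
  }
  out
}

#' Evaluation report for a fitted sparse mixture
#'
#' Collects the summary columns reported for simulation studies: the
#' posterior median \eqn{\hat{e}_0} (when random), \eqn{\hat{K}_0},
#' \eqn{M_0}, the non-permutation rate \eqn{M_{0,\rho}}, the
#' misclassification rate against the true labels (when available) and the
#' Mahalanobis \eqn{MSE_\mu} against the true component parameters (when
#' supplied and the estimated number of components matches), plus the
#' shrinkage-factor summary for normal-gamma runs.
#'
#' @param fit A [fit_sparse_mix()] result.
#' @param truth Optional list with `means` (`K_true x r`) and `covs`
#'   (`r x r x K_true`), e.g. a [mixture_preset()].
#' @return An object of class `eval_report`.
#' @export
evaluate_fit <- function(fit, truth = NULL) {
  stopifnot(inherits(fit, "sfm_fit"))
  trace <- fit$trace
  data <- fit$data
  rep <- list(
    e0_hat = if (trace$e0_random) stats::median(trace$e0) else NA_real_,
    e0_fixed = if (!trace$e0_random) trace$e0[1L] else NA_real_,
    K_hat = fit$k0$mode,
    M0 = fit$k0$M0,
    M0_rho = fit$identified$M0_rho,
    M_tilde = fit$identified$M_tilde,
    MCR = NA_real_,
    MSE_mu = NA_real_,
    lambda_summary = if (!is.null(trace$lam)) shrinkage_summary(trace)
                     else NULL)
  if (!is.null(data$labels_true)) {
    rep$MCR <- misclassification_rate(fit$partition, data$labels_true)
    if (!is.null(truth) && fit$k0$mode == nrow(truth$means)) {
      # align truth with the estimated labels via the MCR matching
      match_idx <- optimal_label_matching(fit$partition, data$labels_true)
      est_lev <- sort(unique(fit$partition))
      tru_lev <- sort(unique(data$labels_true))
      K_hat <- fit$k0$mode
      mu_true <- matrix(NA_real_, K_hat, data$r)
      Sigma_true <- array(NA_real_, c(data$r, data$r, K_hat))
      ok <- TRUE
      for (pos in seq_along(est_lev)) {
        l <- est_lev[pos]
        tpos <- match_idx[pos]
        if (tpos > length(tru_lev)) { ok <- FALSE; break }
        tc <- tru_lev[tpos]
        mu_true[l, ] <- truth$means[tc, ]
        Sigma_true[, , l] <- truth$covs[, , tc]
      }
      if (ok && !anyNA(mu_true))
        rep$MSE_mu <- mse_mu(fit$identified$mu, mu_true, Sigma_true)
    }
  }
  structure(rep, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Sparse finite mixture evaluation\n")
  if (!is.na(x$e0_hat)) cat("  e0_hat (posterior median): ",
                            signif(x$e0_hat, 3L), "\n", sep = "")
  if (!is.na(x$e0_fixed)) cat("  e0 fixed at: ", x$e0_fixed, "\n", sep = "")
  cat("  K0_hat = ", x$K_hat, ", M0 = ", x$M0, ", M0_rho = ",
      signif(x$M0_rho, 4L), "\n", sep = "")
  if (!is.na(x$MCR)) cat("  MCR = ", signif(x$MCR, 4L), "\n", sep = "")
  if (!is.na(x$MSE_mu)) cat("  MSE_mu = ", signif(x$MSE_mu, 4L), "\n",
                            sep = "")
  if (!is.null(x$lambda_summary)) {
    cat("  median shrinkage factors: ",
        paste(signif(x$lambda_summary$quantiles["50%", ], 3L),
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
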