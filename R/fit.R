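#' Fit an identified sparse finite Gaussian mixture
#'
#' The full pipeline: run the Gibbs sampler on a deliberately overfitting
#' mixture, estimate the number of data clusters by the posterior mode of
#' the number of non-empty components, extract the point-process
#' representation of the component-mean draws, resolve label switching by
#' Mahalanobis K-centroids clustering, and derive the final partition of
#' the observations.
#'
#' @param data A [mixture_data()] object.
#' @param K Number of components of the overfitting mixture (ignored when
#'   `prior` is supplied).
#' @param prior Optional [default_priors()] configuration; built from `K`
#'   and `...` when omitted.
#' @param opts An [mcmc_options()] object.
#' @param restarts Restarts of the K-centroids clustering.
#' @param ... Passed to [default_priors()] when `prior` is `NULL`.
#' @return An object of class `sfm_fit`: list with the `trace`, the
#'   [k0_posterior()], the `point_process`, the `centroid_set`, the
#'   `identified_posterior`, the final `partition` (and
#'   `assignment_freq`), and the input `data` and `prior`.
#' @examples
#' \donttest{
#' d <- simulate_mixture(mixture_preset("equal_weights"), N = 300, seed = 1)
#' fit <- fit_sparse_mix(d, K = 8, e0 = 0.01,
#'                       opts = mcmc_options(M = 500, burnin = 200))
#' fit$k0$mode
#' }
#' @export
fit_sparse_mix <- function(data, K = 15, prior = NULL,
                           opts = mcmc_options(), restarts = 10L, ...) {
  stopifnot(inherits(data, "mix_data"))
  if (is.null(prior)) prior <- default_priors(data, K = K, ...)
  trace <- run_mcmc(data, prior, opts)
  k0 <- k0_posterior(trace)
  pps <- extract_point_process(trace, k0$mode)
  cs <- if (k0$mode == 1L) {
    # single cluster: nothing to relabel
    structure(list(centroids = matrix(colMeans(pps$points), 1L),
                   dispersions = array(regularize_spd(stats::cov(pps$points),
                                                      ncol(pps$points)),
                                       c(ncol(pps$points), ncol(pps$points),
                                         1L)),
                   assignment = rep(1L, nrow(pps$points)),
                   objective = 0),
              class = "centroid_set")
  } else {
    kc_for_point_process(pps, restarts = restarts, seed = opts$seed)
  }
  identified <- relabel_trace(trace, pps, cs)
  part <- if (!is.null(identified$S)) final_partition(identified)
          else list(partition = NULL, assignment_freq = NULL)
  structure(
    list(trace = trace, k0 = k0, point_process = pps, centroids = cs,
         identified = identified, partition = part$partition,
         assignment_freq = part$assignment_freq,
         data = data, prior = prior, opts = opts),
    class = "sfm_fit")
}

#' @export
print.sfm_fit <- function(x, ...) {
  cat("Sparse finite Gaussian mixture fit (overfitting K = ", x$prior$K,
      ")\n", sep = "")
  cat("  estimated clusters K0_hat = ", x$k0$mode,
      " (M0 = ", x$k0$M0, " of ", x$trace$M, " sweeps)\n", sep = "")
  cat("  non-permutation rate M0_rho = ",
      signif(x$identified$M0_rho, 4L), "\n", sep = "")
  if (x$trace$e0_random)
    cat("  posterior median e0 = ", signif(stats::median(x$trace$e0), 3L),
        "\n", sep = "")
  if (!is.null(x$partition)) {
    tab <- table(x$partition)
    cat("  partition sizes: ", paste(as.integer(tab), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.sfm_fit <- function(object, truth = NULL, ...) {
  evaluate_fit(object, truth = truth)
}
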