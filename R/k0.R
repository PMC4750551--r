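#' Number of non-empty components in one sweep
#'
#' \eqn{K_0^{(m)} = K - \sum_k I\{N_k^{(m)} = 0\}}: the number of mixture
#' components to which at least one observation is allocated.
#'
#' @param Nk Vector of non-negative occupancy counts.
#' @return Integer count of non-empty components.
#' @examples
#' count_nonempty(c(3, 2, 0)) # 2
#' @export
count_nonempty <- function(Nk) {
  stopifnot(all(Nk >= 0))
  as.integer(sum(Nk > 0))
}

#' Posterior of the number of non-empty components
#'
#' Estimates \eqn{Pr(K_0 = h | y)} for \eqn{h = 1, \ldots, K} by the
#' relative frequency of sweeps with exactly `h` non-empty components, and
#' returns the posterior mode \eqn{\hat{K}_0} (ties broken toward the
#' smaller, more parsimonious value) together with \eqn{M_0}, the number of
#' sweeps at the mode. The full distribution is always reported: the
#' distribution is typically strongly right-skewed, which makes the
#' posterior mean a fragile summary.
#'
#' @param trace An [run_mcmc()] trace, or an integer vector of per-sweep
#'   non-empty-component counts.
#' @param K Total number of components (taken from the trace when omitted).
#' @return An object of class `k0_posterior` with fields `counts` (named
#'   vector over `1:K`), `probs`, `mode` and `M0`.
#' @export
k0_posterior <- function(trace, K = NULL) {
  if (inherits(trace, "sfm_trace")) {
    K0 <- trace$K0
    if (is.null(K)) K <- trace$K
  } else {
    K0 <- as.integer(trace)
    if (is.null(K)) K <- max(K0)
  }
  M <- length(K0)
  stopifnot(M >= 1L, all(K0 >= 1L), all(K0 <= K))
  counts <- tabulate(K0, nbins = K)
  names(counts) <- seq_len(K)
  mode <- which.max(counts)   # which.max takes the first = smallest on ties
  structure(
    list(counts = counts, probs = counts / M,
         mode = as.integer(mode), M0 = counts[[mode]], M = M),
    class = "k0_posterior")
}

#' @export
print.k0_posterior <- function(x, ...) {
  cat("Posterior of the number of non-empty components (M = ", x$M,
      " sweeps)\n", sep = "")
  nz <- x$counts[x$counts > 0L]
  for (h in names(nz))
    cat(sprintf("  K0 = %s: %6d  (%.4f)\n", h, nz[[h]], nz[[h]] / x$M))
  cat("  mode K0_hat = ", x$mode, " with M0 = ", x$M0, "\n", sep = "")
  invisible(x)
}
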