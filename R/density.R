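#' Log density of a multivariate Gaussian component
#'
#' Numerically stable evaluation through the Cholesky factor of `Sigma`.
#' A factorization failure (non-positive-definite `Sigma`) is an error;
#' no silent jitter is applied at the density level.
#'
#' @param y Numeric vector of length `r`, or an `N x r` matrix of
#'   observations in rows.
#' @param mu Component mean, length `r`.
#' @param Sigma Symmetric positive definite `r x r` covariance matrix.
#' @return Log density value(s); a vector of length `N` when `y` is a matrix.
#' @examples
#' log_component_density(0, 0, matrix(1)) # -0.5 * log(2 * pi)
#' @export
log_component_density <- function(y, mu, Sigma) {
  if (is.null(dim(y))) y <- matrix(y, nrow = 1L)
  r <- length(mu)
  stopifnot(ncol(y) == r, nrow(Sigma) == r, ncol(Sigma) == r)
  L <- tryCatch(chol(Sigma),
                error = function(e) stop("'Sigma' is not positive definite"))
  z <- backsolve(L, t(y) - mu, transpose = TRUE)
  -0.5 * r * log(2 * pi) - sum(log(diag(L))) - 0.5 * .colSums(z * z, r, nrow(y))
}

# N x K matrix of component log densities for the current state.
# chol() failures here mean a degenerate component covariance and are
# propagated as errors by log_component_density.
comp_logdens <- function(y, mu, Sigma) {
  K <- nrow(mu)
  out <- matrix(0, nrow(y), K)
  for (k in seq_len(K))
    out[, k] <- log_component_density(y, mu[k, ], Sigma[, , k])
  out
}

#' Closed-form log marginal of the normal-gamma prior in one dimension
#'
#' For the hierarchical shrinkage prior \eqn{\mu_{kj} | \lambda_j \sim
#' N(b_{0j}, \lambda_j R_j^2)}, \eqn{\lambda_j \sim G(\nu_1, \nu_2)}, the
#' scale can be integrated out analytically, giving
#' \deqn{\pi(\mu_{1j},\ldots,\mu_{Kj} | b_0) = \frac{\nu_2^{\nu_1}}
#'   {(2\pi)^{K/2}\Gamma(\nu_1)} \, 2 K_{p_K}(\sqrt{a_j b_j})
#'   \left(\frac{b_j}{a_j}\right)^{p_K/2} \frac{1}{R_j^K},}
#' with \eqn{a_j = 2\nu_2}, \eqn{p_K = \nu_1 - K/2},
#' \eqn{b_j = \sum_k (\mu_{kj} - b_{0j})^2 / R_j^2} and \eqn{K_\alpha}
#' the modified Bessel function of the second kind. (The \eqn{1/R_j^K}
#' factor carries the Jacobian of the per-variable scaling so that the
#' result is a density in the \eqn{\mu_{kj}} themselves.)
#'
#' @param mu_col Numeric vector \eqn{(\mu_{1j}, \ldots, \mu_{Kj})}.
#' @param b0j Prior location in dimension `j`.
#' @param nu1,nu2 Gamma shape and rate of the shrinkage-factor prior.
#' @param Rj Data range in dimension `j`.
#' @return The log marginal prior density (finite for `b_j > 0`). For the
#'   degenerate boundary `b_j = 0` the analytic limit is returned when
#'   `p_K > 0`; otherwise an error is signalled.
#' @export
normal_gamma_log_marginal <- function(mu_col, b0j, nu1, nu2, Rj) {
  stopifnot(nu1 > 0, nu2 > 0, Rj > 0)
  K <- length(mu_col)
  aj <- 2 * nu2
  pK <- nu1 - K / 2
  bj <- sum((mu_col - b0j)^2) / Rj^2
  base <- nu1 * log(nu2) - (K / 2) * log(2 * pi) - lgamma(nu1) - K * log(Rj)
  if (bj == 0) {
    if (pK <= 0)
      stop("degenerate limit b_j = 0 with p_K <= 0: marginal diverges")
    # 2 K_p(x) (x/a)^p -> Gamma(p) (2/a)^p as x -> 0+, p > 0
    return(base + lgamma(pK) + pK * log(2 / aj))
  }
  base + log(2) + log_besselK(sqrt(aj * bj), pK) +
    (pK / 2) * (log(bj) - log(aj))
}

# log K_nu(x) without under/overflow; besselK's exponential scaling handles
# large x, a small-argument expansion handles x near 0 where besselK
# overflows for moderate |nu|.
log_besselK <- function(x, nu) {
  nu <- abs(nu)  # K_{-nu} = K_nu
  if (x < 1e-6 && nu > 0) {
    # K_nu(x) ~ Gamma(nu)/2 * (2/x)^nu
    return(lgamma(nu) - log(2) + nu * (log(2) - log(x)))
  }
  b <- besselK(x, nu, expon.scaled = TRUE)
  if (!is.finite(b) || b <= 0)
    stop("besselK evaluation failed at x = ", x, ", nu = ", nu)
  log(b) - x
}
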