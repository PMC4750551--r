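#' Data-dependent default priors for a sparse finite Gaussian mixture
#'
#' Builds the full prior configuration for an overfitting mixture with `K`
#' components. Weights get a symmetric Dirichlet prior
#' \eqn{\eta \sim Dir(e_0, \ldots, e_0)} where \eqn{e_0} is either fixed at
#' a small value or given the hyperprior \eqn{e_0 \sim G(a, aK)} (prior mean
#' \eqn{1/K}, matching a Dirichlet-process approximation with unit
#' concentration). Component means get either the standard conditionally
#' conjugate prior \eqn{\mu_k \sim N(b_0, R_0)} with
#' \eqn{b_0 = \mathrm{median}(y)} and \eqn{R_0 = Diag(R_1^2,\ldots,R_r^2)},
#' or the hierarchical normal-gamma shrinkage prior
#' \eqn{\mu_k \sim N(b_0, \Lambda R_0 \Lambda)},
#' \eqn{\Lambda = Diag(\sqrt{\lambda_1},\ldots,\sqrt{\lambda_r})},
#' \eqn{\lambda_j \sim G(\nu_1, \nu_2)}, \eqn{b_0 \sim N(m_0, M_0)} with the
#' improper choice \eqn{M_0^{-1} = 0}. Component precisions get the
#' hierarchical Wishart prior \eqn{\Sigma_k^{-1} \sim W(c_0, C_0)},
#' \eqn{C_0 \sim W(g_0, G_0)} with \eqn{c_0 = 2.5 + (r-1)/2},
#' \eqn{g_0 = 0.5 + (r-1)/2} and
#' \eqn{G_0 = (100 g_0/c_0)\, Diag(1/R_1^2, \ldots, 1/R_r^2)}.
#'
#' The Wishart is parameterized throughout the package as \eqn{W(\nu,
#' \Lambda)} with density proportional to
#' \eqn{|X|^{\nu-(r+1)/2} \exp(-tr(\Lambda X))}, so that
#' \eqn{E[X] = \nu \Lambda^{-1}}.
#'
#' @param data A [mixture_data()] object.
#' @param K Number of mixture components of the (deliberately overfitting)
#'   mixture.
#' @param mean_prior `"standard"` or `"normalgamma"`.
#' @param e0 Either a single positive number (fixed Dirichlet hyperparameter)
#'   or the string `"gamma"` for the hyperprior \eqn{G(a, aK)}.
#' @param a Shape of the gamma hyperprior on `e0` (used when `e0 = "gamma"`).
#' @param nu1,nu2 Shape and rate of the gamma prior on the shrinkage factors
#'   \eqn{\lambda_j} (normal-gamma prior only).
#' @return An object of class `mix_prior`.
#' @examples
#' d <- mixture_data(matrix(rnorm(400), 100, 4))
#' p <- default_priors(d, K = 15, mean_prior = "standard", e0 = "gamma")
#' p$c0  # 4 when r = 4
#' @export
default_priors <- function(data, K, mean_prior = c("standard", "normalgamma"),
                           e0 = "gamma", a = 10, nu1 = 0.5, nu2 = 0.5) {
  stopifnot(inherits(data, "mix_data"))
  K <- as.integer(K)
  if (K < 1L) stop("'K' must be at least 1")
  mean_prior <- match.arg(mean_prior)
  if (identical(e0, "gamma")) {
    if (!is.numeric(a) || a <= 0) stop("'a' must be positive")
    e0_spec <- list(kind = "gamma", a = a, rate = a * K)
  } else {
    if (!is.numeric(e0) || length(e0) != 1L || e0 <= 0)
      stop("'e0' must be a single positive number or \"gamma\"")
    e0_spec <- list(kind = "fixed", value = e0)
  }
  if (nu1 <= 0 || nu2 <= 0) stop("'nu1' and 'nu2' must be positive")
  r <- data$r
  c0 <- 2.5 + (r - 1) / 2
  g0 <- 0.5 + (r - 1) / 2
  structure(
    list(K = K,
         mean_prior = mean_prior,
         e0_spec = e0_spec,
         nu1 = nu1, nu2 = nu2,
         m0 = data$med,
         M0_inv = matrix(0, r, r),   # improper flat prior on b0
         b0_fixed = data$med,
         R0_diag = data$R^2,
         c0 = c0, g0 = g0,
         G0 = diag(100 * g0 / c0 / data$R^2, r, r),
         r = r),
    class = "mix_prior")
}

#' @export
print.mix_prior <- function(x, ...) {
  cat("Sparse finite mixture prior (K = ", x$K, ")\n", sep = "")
  cat("  means: ", if (x$mean_prior == "standard") "standard N(b0, R0)"
      else sprintf("normal-gamma shrinkage (nu1 = %g, nu2 = %g)",
                   x$nu1, x$nu2), "\n", sep = "")
  if (x$e0_spec$kind == "fixed")
    cat("  weights: Dir(e0) with e0 fixed at ", x$e0_spec$value, "\n",
        sep = "")
  else
    cat("  weights: Dir(e0), e0 ~ G(", x$e0_spec$a, ", ",
        x$e0_spec$rate, ") [prior mean ", signif(1 / x$K, 3L), "]\n",
        sep = "")
  cat("  covariances: Sigma_k^-1 ~ W(c0 = ", x$c0, ", C0), C0 ~ W(g0 = ",
      x$g0, ", G0)\n", sep = "")
  invisible(x)
}

# B0 diagonal for the current shrinkage state (lam ignored under the
# standard prior).
b0_var_diag <- function(prior, lam) {
  if (prior$mean_prior == "normalgamma") prior$R0_diag * lam
  else prior$R0_diag
}
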