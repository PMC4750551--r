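#' Generalized inverse Gaussian random variates
#'
#' Draws from the GIG distribution with density
#' \deqn{f(x) \propto x^{p-1} \exp\{-(a x + b / x)/2\}, \quad x > 0,}
#' the full conditional of the shrinkage factors \eqn{\lambda_j} under the
#' normal-gamma prior. The parameterization matches the triple
#' \eqn{(a_j, b_j, p_K)} of the shrinkage-factor posterior: `a` multiplies
#' `x` and `b` multiplies `1/x` inside the exponent.
#'
#' Sampling uses the ratio-of-uniforms method on the two-parameter standard
#' form (scale \eqn{\sqrt{b/a}} factored out, all bounds computed in log
#' space), after reducing `p < 0` through the reciprocal identity
#' \eqn{X \sim GIG(a, b, p) \Leftrightarrow 1/X \sim GIG(b, a, -p)}.
#' Valid for all `p` with `a > 0, b > 0`, and for `b = 0` with `p > 0`
#' (gamma limit) or `a = 0` with `p < 0` (inverse-gamma limit).
#'
#' @param n Number of draws.
#' @param a Non-negative rate on `x` (positive unless `p < 0`).
#' @param b Non-negative rate on `1/x` (positive unless `p > 0`).
#' @param p Real order parameter.
#' @return Numeric vector of `n` strictly positive draws.
#' @examples
#' set.seed(1)
#' mean(rgig(1e4, a = 1, b = 2, p = -1.5))
#' @export
rgig <- function(n, a, b, p) {
  stopifnot(length(a) == 1L, length(b) == 1L, length(p) == 1L,
            a >= 0, b >= 0)
  if (p < 0) return(1 / rgig(n, a = b, b = a, p = -p))
  if (b == 0) {
    if (p <= 0) stop("degenerate GIG: b = 0 requires p > 0")
    if (a <= 0) stop("degenerate GIG: a and b cannot both be 0")
    return(stats::rgamma(n, shape = p, rate = a / 2))
  }
  if (a <= 0) stop("degenerate GIG: a = 0 requires p < 0")
  s <- sqrt(b / a)            # scale of the two-parameter standard form
  omega <- sqrt(a * b)
  s * vapply(seq_len(n), function(i) rgig_std1(p, omega), numeric(1L))
}

# One draw from the two-parameter GIG: density prop. to
# z^(p-1) exp(-omega (z + 1/z) / 2), p >= 0, omega > 0.
# Plain ratio of uniforms, bounds in log scale relative to the mode.
rgig_std1 <- function(p, omega) {
  lh <- function(z) (p - 1) * log(z) - 0.5 * omega * (z + 1 / z)
  # mode of h and of z^2 h, written to be stable for p < 1
  gig_mode <- function(q) {
    if (q >= 1) ((q - 1) + sqrt((q - 1)^2 + omega^2)) / omega
    else omega / ((1 - q) + sqrt((1 - q)^2 + omega^2))
  }
  zm <- gig_mode(p)
  zv <- gig_mode(p + 2)
  log_umax <- 0.5 * lh(zm)
  log_vmax <- log(zv) + 0.5 * lh(zv)
  ratio <- exp(log_vmax - log_umax)
  for (it in seq_len(1e6L)) {
    u <- stats::runif(1L)
    v <- stats::runif(1L)
    z <- ratio * v / u
    if (2 * (log(u) + log_umax) <= lh(z)) return(z)
  }
  stop("ratio-of-uniforms rejection failed to accept (p = ", p,
       ", omega = ", omega, ")")
}
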