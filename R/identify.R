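#' Point-process representation of the component-mean draws
#'
#' Stacks the mean draws of all non-empty components from the sweeps whose
#' number of non-empty components equals `K_hat`, discarding draws from
#' empty components (whose means are prior draws) and sweeps conditioned on
#' a "wrong" model. The result is an unordered point set in \eqn{R^r},
#' invariant to label switching, with one point per non-empty component per
#' contributing sweep.
#'
#' @param trace An [run_mcmc()] trace.
#' @param K_hat Estimated number of non-empty components (usually the mode
#'   of [k0_posterior()]).
#' @return An object of class `point_process` with `points`
#'   (`(K_hat * M0) x r` matrix), `sweep` and `comp` provenance vectors, and
#'   `M0`, the number of contributing sweeps.
#' @export
extract_point_process <- function(trace, K_hat) {
  stopifnot(inherits(trace, "sfm_trace"))
  keep <- which(trace$K0 == K_hat)
  M0 <- length(keep)
  if (M0 == 0L) stop("no sweeps at the estimated K0 = ", K_hat)
  r <- trace$r
  # non-empty (component, sweep) pairs, sweep-major so that each kept sweep
  # occupies K_hat consecutive rows
  occ <- which(t(trace$Nk[keep, , drop = FALSE]) > 0L)
  comp_idx <- as.integer((occ - 1L) %% trace$K + 1L)
  sweep_idx <- keep[(occ - 1L) %/% trace$K + 1L]
  n_pts <- K_hat * M0
  gather <- cbind(rep(sweep_idx, r), rep(comp_idx, r),
                  rep(seq_len(r), each = n_pts))
  points <- matrix(trace$mu[gather], n_pts, r)
  structure(list(points = points, sweep = sweep_idx, comp = comp_idx,
                 M0 = M0, K_hat = as.integer(K_hat)),
            class = "point_process")
}

#' K-centroids cluster analysis with Mahalanobis distances
#'
#' Partitions points into `K` clusters described by a centroid and a
#' cluster-specific dispersion matrix, minimizing the sum of Mahalanobis
#' distances \eqn{d_{S_k}(x_i, c_k) = \sqrt{(x_i - c_k)' S_k^{-1}
#' (x_i - c_k)}} of each point to its assigned centroid. Iterates
#' assignment (nearest centroid under its own dispersion) and update
#' (within-cluster mean and covariance) until the assignment stabilizes;
#' the recorded objective is guarded to be non-increasing (an update that
#' would increase it stops the loop, keeping the previous solution). The
#' best of `restarts` seedings is returned; each restart seeds centroids
#' by greedy farthest-point selection and stabilizes the partition under
#' the pooled-covariance metric before fitting cluster-specific
#' dispersions. With all dispersions fixed at the identity, one
#' assignment step is exactly the Euclidean K-means assignment.
#'
#' @param points Numeric matrix of points in rows.
#' @param K Number of clusters.
#' @param init Optional list with elements `centroids` (`K x n`) and
#'   `dispersions` (`n x n x K`) to use as the single starting solution.
#' @param max_iter Iteration cap per restart.
#' @param restarts Number of random restarts (ignored when `init` given).
#' @param seed Integer seed for the restarts.
#' @param fixed_dispersion Optional single `n x n` matrix; when supplied
#'   the dispersions are held fixed at it (identity gives Euclidean
#'   K-means-style clustering).
#' @return An object of class `centroid_set` with `centroids`,
#'   `dispersions`, `assignment` and `objective`.
#' @export
k_centroids_mahalanobis <- function(points, K, init = NULL, max_iter = 100L,
                                    restarts = 10L, seed = 1L,
                                    fixed_dispersion = NULL) {
  stopifnot(is.matrix(points), nrow(points) >= K)
  if (nrow(unique(points)) < K)
    stop("need at least K distinct points")
  set.seed(as.integer(seed))
  best <- NULL
  starts <- if (is.null(init)) seq_len(restarts) else 1L
  for (s in starts) {
    cs <- if (is.null(init)) kc_seed(points, K) else init
    if (is.null(init) && is.null(fixed_dispersion)) {
      # warm start under the pooled-covariance metric (undoes elongation
      # shared across clusters) before fitting cluster-specific dispersions
      n <- ncol(points)
      pooled <- regularize_spd(stats::cov(points), n)
      warm <- kc_run(points, K, cs, max_iter, fixed_dispersion = pooled)
      disp <- array(NA_real_, c(n, n, K))
      for (k in seq_len(K)) {
        rows <- points[warm$assignment == k, , drop = FALSE]
        Sk <- if (nrow(rows) >= 2L) stats::cov(rows) else diag(n)
        disp[, , k] <- regularize_spd(Sk, n)
      }
      cs <- list(centroids = warm$centroids, dispersions = disp)
    }
    res <- kc_run(points, K, cs, max_iter, fixed_dispersion)
    if (is.null(best) || res$objective < best$objective) best <- res
  }
  structure(best, class = "centroid_set")
}

# greedy farthest-point seeding: random first centroid, then repeatedly the
# point farthest (Euclidean) from the chosen set; dispersions start at the
# pooled covariance
kc_seed <- function(points, K) {
  n <- ncol(points)
  idx <- sample.int(nrow(points), 1L)
  for (k in seq_len(K - 1L)) {
    d2 <- vapply(seq_len(nrow(points)), function(i)
      min(colSums((t(points[idx, , drop = FALSE]) - points[i, ])^2)),
      numeric(1L))
    idx <- c(idx, which.max(d2))
  }
  pooled <- regularize_spd(stats::cov(points), n)
  list(centroids = points[idx, , drop = FALSE],
       dispersions = array(pooled, c(n, n, K)))
}

# Sk <- Sk + eps * tr(Sk)/n * I, and a deterministic floor if that is still
# not positive definite (degenerate within-cluster scatter)
regularize_spd <- function(S, n, eps = 1e-8) {
  S <- (S + t(S)) / 2
  tr <- sum(diag(S))
  if (!is.finite(tr) || tr <= 0) tr <- n
  S <- S + diag(eps * tr / n, n)
  while (inherits(tryCatch(chol(S), error = identity), "error"))
    S <- S + diag(max(eps * tr / n, 1e-12), n)
  S
}

kc_distances <- function(points, centroids, dispersions) {
  K <- nrow(centroids)
  d <- matrix(NA_real_, nrow(points), K)
  for (k in seq_len(K)) {
    L <- chol(dispersions[, , k])
    z <- backsolve(L, t(points) - centroids[k, ], transpose = TRUE)
    d[, k] <- sqrt(.colSums(z * z, nrow(z), ncol(z)))
  }
  d
}

kc_run <- function(points, K, cs, max_iter, fixed_dispersion = NULL) {
  n <- ncol(points)
  centroids <- cs$centroids
  dispersions <- cs$dispersions
  if (!is.null(fixed_dispersion))
    dispersions <- array(fixed_dispersion, c(n, n, K))
  assignment <- integer(nrow(points))
  objective <- Inf
  for (it in seq_len(max_iter)) {
    d <- kc_distances(points, centroids, dispersions)
    new_assignment <- max.col(-d, ties.method = "first")
    # re-seed empty clusters from the farthest point
    for (k in seq_len(K)) {
      if (!any(new_assignment == k)) {
        far <- which.max(d[cbind(seq_len(nrow(d)),
                                 new_assignment)])
        new_assignment[far] <- k
        centroids[k, ] <- points[far, ]
      }
    }
    new_objective <- sum(kc_distances(points, centroids,
                                      dispersions)[cbind(seq_along(new_assignment),
                                                         new_assignment)])
    if (new_objective > objective + 1e-12) break  # guard: keep previous
    converged <- identical(new_assignment, assignment)
    assignment <- new_assignment
    objective <- new_objective
    if (converged) break
    for (k in seq_len(K)) {
      rows <- points[assignment == k, , drop = FALSE]
      centroids[k, ] <- colMeans(rows)
      if (is.null(fixed_dispersion)) {
        Sk <- if (nrow(rows) >= 2L) stats::cov(rows) else diag(n)
        dispersions[, , k] <- regularize_spd(Sk, n)
      }
    }
  }
  list(centroids = centroids, dispersions = dispersions,
       assignment = assignment, objective = objective)
}

#' @export
print.centroid_set <- function(x, ...) {
  cat("K-centroids solution: ", nrow(x$centroids), " clusters, objective ",
      signif(x$objective, 6L), "\n", sep = "")
  invisible(x)
}

# Fraction of contributing sweeps whose cluster labels fail to form a
# permutation of 1..K_hat, given a candidate assignment of the stacked
# points. The separation diagnostic of the method, computed without
# relabeling.
nonpermutation_rate <- function(pps, assignment) {
  mean(!sweep_is_permutation(pps, assignment))
}

# logical vector over the M0 contributing sweeps: do the sweep's K_hat
# cluster labels form a permutation of 1..K_hat? Points are stacked
# sweep-major (K_hat consecutive rows per sweep).
sweep_is_permutation <- function(pps, assignment) {
  A <- matrix(assignment, nrow = pps$K_hat)
  ok <- rep(TRUE, ncol(A))
  for (l in seq_len(pps$K_hat)) ok <- ok & (.colSums(A == l, nrow(A), ncol(A)) == 1L)
  ok
}

# Candidate K-centroids solutions for the point process: the default
# farthest-point restarts plus inits whose centroids are single-sweep
# transversals (each contributing sweep holds exactly one draw per
# component, so its K_hat points are a perfect one-per-cluster seed).
# The winner minimizes the non-permutation rate, ties broken by objective.
kc_for_point_process <- function(pps, restarts = 10L, seed = 1L) {
  points <- pps$points
  K_hat <- pps$K_hat
  n <- ncol(points)
  cands <- list(k_centroids_mahalanobis(points, K = K_hat,
                                        restarts = restarts, seed = seed))
  set.seed(as.integer(seed) + 1L)
  sweeps <- unique(pps$sweep)
  pooled <- regularize_spd(stats::cov(points), n)
  for (m in sample(sweeps, min(length(sweeps), restarts))) {
    init <- list(centroids = points[pps$sweep == m, , drop = FALSE],
                 dispersions = array(pooled, c(n, n, K_hat)))
    cands[[length(cands) + 1L]] <-
      k_centroids_mahalanobis(points, K = K_hat, init = init)
  }
  rates <- vapply(cands, function(cs) nonpermutation_rate(pps, cs$assignment),
                  numeric(1L))
  objs <- vapply(cands, `[[`, numeric(1L), "objective")
  cands[[order(rates, objs)[1L]]]
}

#' Relabel the trace from a point-process clustering
#'
#' For every sweep contributing to the point process, collects the cluster
#' labels assigned to its non-empty component draws. Sweeps whose labels
#' form a permutation of \eqn{\{1, \ldots, \hat{K}_0\}} are reordered
#' accordingly (means, covariances, weights and, when stored, allocations);
#' the others are discarded. The fraction discarded is the non-permutation
#' rate \eqn{M_{0,\rho}}, a diagnostic of how well separated the component
#' posteriors are in the point-process representation.
#'
#' @param trace An [run_mcmc()] trace.
#' @param pps The [extract_point_process()] sample.
#' @param cs The [k_centroids_mahalanobis()] solution on `pps$points`.
#' @return An object of class `identified_posterior` with relabeled draw
#'   arrays `mu` (`M_tilde x K_hat x r`), `Sigma`, `eta`, optional `S`
#'   (`N x M_tilde`), the retained sweep indices, `M0`, `M0_rho` and
#'   `M_tilde`.
#' @export
relabel_trace <- function(trace, pps, cs) {
  stopifnot(inherits(trace, "sfm_trace"), inherits(pps, "point_process"))
  K_hat <- pps$K_hat
  is_perm <- sweep_is_permutation(pps, cs$assignment)
  M_tilde <- sum(is_perm)
  M0_rho <- 1 - M_tilde / pps$M0
  if (M_tilde == 0L)
    stop("no identified sweeps: every clustering failed to be a permutation")
  r <- trace$r
  # sweep-major blocks: row block i of the point process belongs to the
  # i-th contributing sweep
  sweep_of_block <- matrix(pps$sweep, nrow = K_hat)[1L, ]
  keep_sweeps <- sweep_of_block[is_perm]
  comp_m <- matrix(pps$comp, nrow = K_hat)[, is_perm, drop = FALSE]
  new_m <- matrix(cs$assignment, nrow = K_hat)[, is_perm, drop = FALSE]
  # ord[l, i]: original component carrying new label l in retained sweep i
  ord <- matrix(0L, K_hat, M_tilde)
  ord[cbind(as.vector(new_m), rep(seq_len(M_tilde), each = K_hat))] <-
    as.vector(comp_m)
  # vectorized gathers
  i_rep <- rep(seq_len(M_tilde), K_hat)           # retained sweep index
  m_rep <- keep_sweeps[i_rep]                     # trace sweep index
  k_new <- rep(seq_len(K_hat), each = M_tilde)
  k_old <- ord[cbind(k_new, i_rep)]
  mu <- array(NA_real_, c(M_tilde, K_hat, r))
  mu[cbind(rep(i_rep, r), rep(k_new, r),
           rep(seq_len(r), each = M_tilde * K_hat))] <-
    trace$mu[cbind(rep(m_rep, r), rep(k_old, r),
                   rep(seq_len(r), each = M_tilde * K_hat))]
  Sigma <- array(NA_real_, c(r, r, K_hat, M_tilde))
  rr <- r * r
  for (l in seq_len(K_hat)) {
    src <- (m_rep[k_new == l] - 1L) * (rr * trace$K) +
      (k_old[k_new == l] - 1L) * rr
    dst <- (seq_len(M_tilde) - 1L) * (rr * K_hat) + (l - 1L) * rr
    idx <- rep(src, each = rr) + seq_len(rr)
    Sigma[rep(dst, each = rr) + seq_len(rr)] <- trace$Sigma[idx]
  }
  eta <- matrix(NA_real_, M_tilde, K_hat)
  eta[cbind(i_rep, k_new)] <- trace$eta[cbind(m_rep, k_old)]
  S <- NULL
  if (!is.null(trace$S)) {
    # relab[k, i]: new label of original component k in retained sweep i
    relab <- matrix(0L, trace$K, M_tilde)
    relab[cbind(as.vector(comp_m), rep(seq_len(M_tilde), each = K_hat))] <-
      as.vector(new_m)
    S_old <- trace$S[, keep_sweeps, drop = FALSE]
    S <- matrix(relab[cbind(as.vector(S_old),
                            rep(seq_len(M_tilde), each = trace$N))],
                trace$N, M_tilde)
  }
  structure(
    list(mu = mu, Sigma = Sigma, eta = eta, S = S,
         sweeps = keep_sweeps, K_hat = K_hat,
         M0 = pps$M0, M0_rho = M0_rho, M_tilde = M_tilde),
    class = "identified_posterior")
}

#' @export
print.identified_posterior <- function(x, ...) {
  cat("Identified posterior: K0_hat = ", x$K_hat, ", M0 = ", x$M0,
      ", non-permutation rate = ", signif(x$M0_rho, 4L),
      " (", x$M_tilde, " identified sweeps)\n", sep = "")
  invisible(x)
}

#' Final partition of the observations
#'
#' Assigns each observation to the component it was allocated to most often
#' among the identified (uniquely relabeled) sweeps; ties break toward the
#' smaller label.
#'
#' @param identified An [relabel_trace()] result with stored allocations.
#' @return List with `partition` (integer N-vector) and `assignment_freq`
#'   (`N x K_hat` matrix of per-observation assignment frequencies, rows
#'   summing to 1).
#' @export
final_partition <- function(identified) {
  stopifnot(inherits(identified, "identified_posterior"))
  if (is.null(identified$S))
    stop("allocations were not stored; rerun with store_allocations = TRUE")
  K_hat <- identified$K_hat
  N <- nrow(identified$S)
  freq <- matrix(0, N, K_hat)
  for (l in seq_len(K_hat))
    freq[, l] <- .rowSums(identified$S == l, N, ncol(identified$S))
  freq <- freq / identified$M_tilde
  list(partition = max.col(freq, ties.method = "first"),
       assignment_freq = freq)
}
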