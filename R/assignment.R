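# Minimum-cost perfect matching on a square cost matrix (Hungarian
# algorithm, O(n^3) shortest-augmenting-path form with potentials).
# Used for optimally matching estimated to true cluster labels; rectangular
# confusion matrices are padded with zero rows/columns by the callers.
# Returns an integer vector: column assigned to each row.
solve_assignment <- function(cost) {
  stopifnot(is.matrix(cost), nrow(cost) == ncol(cost), all(is.finite(cost)))
  n <- nrow(cost)
  # +1 shift everywhere: index 1 holds a virtual row/column 0
  u <- numeric(n + 1L)
  v <- numeric(n + 1L)
  p <- integer(n + 1L)    # p[j+1]: row currently matched to column j
  way <- integer(n + 1L)  # way[j+1]: predecessor column on the alternating path
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
          if (cur < minv[j + 1L]) {
            minv[j + 1L] <- cur
            way[j + 1L] <- j0
          }
          if (minv[j + 1L] < delta) {
            delta <- minv[j + 1L]
            j1 <- j
          }
        }
      }
      for (j in 0L:n) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(n)) if (p[j + 1L] > 0L) assignment[p[j + 1L]] <- j
  assignment
}
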