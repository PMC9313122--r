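# Shared fixtures and independent oracles.

# Small cohort for fast model tests.
small_cohort <- function(seed = 1, n_zpdx = 10, embryos_per_arm = 6, ...) {
  simulate_cohort(sim_params(n_zpdx = n_zpdx, embryos_per_arm = embryos_per_arm,
                             engraftment_failure_rate = 0, ...),
                  seed = seed)
}

small_derived <- function(seed = 1, ...) {
  derive_volume_changes(small_cohort(seed = seed, ...)$measurements)
}

# Exhaustive-partition oracle: minimum within-cluster sum of squares over
# every partition of the rows of X into exactly k non-empty clusters.
brute_force_wcss <- function(X, k) {
  n <- nrow(X)
  stopifnot(n <= 9)
  assignments <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  best <- Inf
  for (r in seq_len(nrow(assignments))) {
    a <- assignments[r, ]
    if (length(unique(a)) != k) next
    w <- 0
    for (c in unique(a)) {
      rows <- X[a == c, , drop = FALSE]
      ctr <- colMeans(rows)
      w <- w + sum(sweep(rows, 2, ctr)^2)
    }
    if (w < best) best <- w
  }
  best
}

# Definitional O(n^2) pair-count oracle for Kendall's S.
brute_force_S <- function(x, y) {
  n <- length(x); nc <- 0L; nd <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
    if (s > 0) nc <- nc + 1L else if (s < 0) nd <- nd + 1L
  }
  list(S = nc - nd, nc = nc, nd = nd)
}
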