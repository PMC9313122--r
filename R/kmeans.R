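# Hartigan-Wong k-means, implemented from scratch.
#
# The transfer algorithm alternates an optimal-transfer stage (every point is
# tested against every other cluster) and a quick-transfer stage (each point
# is tested only against its recorded second-closest cluster), both using the
# size-weighted cost test: moving point x from cluster a (size na) to b
# (size nb) decreases the within-cluster sum of squares iff
#   nb * d(x, cb)^2 / (nb + 1)  <  na * d(x, ca)^2 / (na - 1).
# Centers and counts are updated incrementally after each accepted transfer,
# so every pass is monotone in the objective.

.sq_dist <- function(x, center) sum((x - center)^2)

.wcss_of <- function(X, assign, centers) {
  sum(vapply(seq_len(nrow(X)), function(i) .sq_dist(X[i, ], centers[assign[i], ]),
             numeric(1)))
}

# One full run from sampled initial centers; X is a numeric matrix.
.hw_run <- function(X, k, init_rows) {
  n <- nrow(X)
  centers <- X[init_rows, , drop = FALSE]
  # initial assignment: nearest (IC1) and second-nearest (IC2) centers
  d2 <- vapply(seq_len(k), function(c) {
    rowSums((X - matrix(centers[c, ], n, ncol(X), byrow = TRUE))^2)
  }, numeric(n))
  d2 <- matrix(d2, nrow = n)
  ic1 <- max.col(-d2, ties.method = "first")
  d2_masked <- d2
  d2_masked[cbind(seq_len(n), ic1)] <- Inf
  ic2 <- max.col(-d2_masked, ties.method = "first")

  counts <- tabulate(ic1, nbins = k)
  repaired <- 0L
  # empty-cluster repair: seed with the point farthest from its center
  while (any(counts == 0)) {
    empty <- which(counts == 0)[1]
    dist_own <- vapply(seq_len(n), function(i) .sq_dist(X[i, ], centers[ic1[i], ]),
                       numeric(1))
    dist_own[counts[ic1] <= 1] <- -Inf
    far <- which.max(dist_own)
    counts[ic1[far]] <- counts[ic1[far]] - 1L
    ic1[far] <- empty
    counts[empty] <- 1L
    repaired <- repaired + 1L
  }
  for (c in seq_len(k))
    centers[c, ] <- colMeans(X[ic1 == c, , drop = FALSE])

  transfer <- function(i, from, to) {
    nf <- counts[from]; nt <- counts[to]
    centers[from, ] <<- (centers[from, ] * nf - X[i, ]) / (nf - 1)
    centers[to, ] <<- (centers[to, ] * nt + X[i, ]) / (nt + 1)
    counts[from] <<- nf - 1L
    counts[to] <<- nt + 1L
    ic2[i] <<- from
    ic1[i] <<- to
  }

  max_sweeps <- 200L
  for (sweep in seq_len(max_sweeps)) {
    moved_optimal <- FALSE
    # optimal-transfer stage
    for (i in seq_len(n)) {
      from <- ic1[i]
      if (counts[from] <= 1) next
      r1 <- counts[from] * .sq_dist(X[i, ], centers[from, ]) / (counts[from] - 1)
      best_to <- 0L; best_cost <- r1
      for (c in seq_len(k)) {
        if (c == from) next
        cost <- counts[c] * .sq_dist(X[i, ], centers[c, ]) / (counts[c] + 1)
        if (cost < best_cost) { best_cost <- cost; best_to <- c }
      }
      if (best_to > 0L) {
        transfer(i, from, best_to)
        moved_optimal <- TRUE
      } else {
        # keep IC2 current for the quick-transfer stage
        alt <- vapply(seq_len(k), function(c)
          if (c == from) Inf else .sq_dist(X[i, ], centers[c, ]), numeric(1))
        ic2[i] <- which.min(alt)
      }
    }
    if (!moved_optimal) break
    # quick-transfer stage: only IC1 <-> IC2 swaps until stable
    repeat {
      moved_quick <- FALSE
      for (i in seq_len(n)) {
        from <- ic1[i]; to <- ic2[i]
        if (counts[from] <= 1) next
        r1 <- counts[from] * .sq_dist(X[i, ], centers[from, ]) / (counts[from] - 1)
        r2 <- counts[to] * .sq_dist(X[i, ], centers[to, ]) / (counts[to] + 1)
        if (r2 < r1) {
          transfer(i, from, to)
          moved_quick <- TRUE
        }
      }
      if (!moved_quick) break
    }
  }
  list(assign = ic1, centers = centers,
       wcss = .wcss_of(X, ic1, centers), repaired = repaired)
}

# Relabel clusters in order of first-occurring member so output is stable
# under restart order and center permutation.
.canonicalize <- function(assign, centers) {
  first <- vapply(seq_len(nrow(centers)), function(c) match(c, assign),
                  numeric(1))
  ord <- order(first)
  remap <- match(seq_along(ord), ord)
  list(assign = remap[assign], centers = centers[ord, , drop = FALSE])
}

#' Hartigan-Wong k-means
#'
#' From-scratch implementation of the Hartigan-Wong transfer algorithm for
#' k-means: points move between clusters whenever the size-weighted
#' `n/(n+1)`-vs-`n/(n-1)` cost test lowers the within-cluster sum of squares,
#' alternating full optimal-transfer sweeps with quick-transfer sweeps over
#' each point's second-closest cluster. The best of `n_restarts` random
#' initializations (centers sampled without replacement from the rows) is
#' returned; given `seed`, the result is reproducible. An empty cluster
#' arising during initialization is re-seeded with the point farthest from
#' its center.
#'
#' @param X Numeric matrix (rows = objects, e.g. the [response_matrix()] of
#'   avatars). Row names are preserved in the assignment.
#' @param k Number of clusters, `1 <= k <= nrow(X)`.
#' @param n_restarts Random restarts (default 50).
#' @param seed Integer seed for the restarts; `NULL` leaves the RNG state
#'   alone.
#' @param scale Standardize columns before clustering (default `FALSE`; all
#'   response-profile columns already share the transformed outcome scale).
#' @return An object of class `"hw_kmeans"`: `assignments` (named integer
#'   vector, cluster ids `1..k` ordered by first-occurring member), `centers`
#'   (`k x p`), `wcss`, `k`, `n_restarts`, `seed`, `n_repaired`.
#' @examples
#' X <- rbind(matrix(rnorm(20), 10), matrix(rnorm(20, 4), 10))
#' hartigan_wong(X, k = 2, seed = 1)
#' @export
hartigan_wong <- function(X, k, n_restarts = 50, seed = NULL, scale = FALSE) {
  X <- as.matrix(X)
  if (!is.numeric(X) || any(!is.finite(X)))
    stop("'X' must be a finite numeric matrix", call. = FALSE)
  n <- nrow(X)
  if (k < 1 || k > n)
    stop("'k' must be between 1 and nrow(X)", call. = FALSE)
  if (scale) X <- base::scale(X)
  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old_seed)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old_seed, envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  if (k == n) {
    best <- list(assign = seq_len(n), centers = X, wcss = 0, repaired = 0L)
  } else if (k == 1) {
    ctr <- matrix(colMeans(X), 1, ncol(X))
    best <- list(assign = rep(1L, n), centers = ctr,
                 wcss = .wcss_of(X, rep(1L, n), ctr), repaired = 0L)
  } else {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      init <- sample.int(n, k)
      run <- .hw_run(X, k, init)
      if (is.null(best) || run$wcss < best$wcss - 1e-12) best <- run
    }
  }
  canon <- .canonicalize(best$assign, best$centers)
  assignments <- canon$assign
  names(assignments) <- rownames(X)
  structure(list(assignments = assignments, centers = canon$centers,
                 wcss = best$wcss, k = k, n_restarts = n_restarts,
                 seed = seed, n_repaired = best$repaired),
            class = "hw_kmeans")
}

#' @export
print.hw_kmeans <- function(x, ...) {
  cat(sprintf("Hartigan-Wong k-means: k = %d, wcss = %.4f (%d restarts)\n",
              x$k, x$wcss, x$n_restarts))
  sizes <- tabulate(x$assignments, nbins = x$k)
  cat("cluster sizes:", paste(sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Cluster avatars over candidate cluster counts
#'
#' Runs [hartigan_wong()] for each candidate `k` on the avatar
#' response-profile matrix and reports singleton clusters explicitly, so an
#' outlier avatar that "clusters alone" is diagnosed mechanically.
#'
#' @param X Response-profile matrix (see [response_matrix()]).
#' @param k_candidates Integer vector of cluster counts (default `c(4, 5)`).
#' @param n_restarts,seed,scale Passed to [hartigan_wong()].
#' @return Named list (one element per `k`) of `hw_kmeans` objects, each
#'   with a `singletons` element naming avatars in size-1 clusters.
#' @export
cluster_avatars <- function(X, k_candidates = c(4, 5), n_restarts = 50,
                            seed = NULL, scale = FALSE) {
  out <- lapply(k_candidates, function(k) {
    res <- hartigan_wong(X, k, n_restarts = n_restarts, seed = seed,
                         scale = scale)
    sizes <- tabulate(res$assignments, nbins = k)
    singles <- which(sizes == 1)
    res$singletons <- names(res$assignments)[res$assignments %in% singles]
    res
  })
  names(out) <- paste0("k", k_candidates)
  out
}

#' Principal-component projection of avatar response profiles
#'
#' Column-centered SVD scores for display of the clustering. Component signs
#' follow the convention that each loading vector's largest-magnitude entry
#' is positive, so scores are reproducible across platforms.
#'
#' @param X Numeric matrix with at least 2 columns.
#' @param n_components Number of components to return (default 2).
#' @return List with `scores` (n x n_components), `loadings`,
#'   `sdev` (component standard deviations) and `center`.
#' @export
pca_project <- function(X, n_components = 2) {
  X <- as.matrix(X)
  if (ncol(X) < 2) stop("need at least 2 columns", call. = FALSE)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  if (all(abs(Xc) < 1e-12)) {
    message("constant matrix: all principal-component scores are zero")
    sc <- matrix(0, nrow(X), n_components,
                 dimnames = list(rownames(X), paste0("PC", seq_len(n_components))))
    return(list(scores = sc,
                loadings = matrix(0, ncol(X), n_components),
                sdev = rep(0, n_components), center = ctr))
  }
  sv <- svd(Xc)
  n_components <- min(n_components, length(sv$d))
  flip <- vapply(seq_len(n_components), function(j) {
    v <- sv$v[, j]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, numeric(1))
  scores <- sweep(sv$u[, seq_len(n_components), drop = FALSE] %*%
                    diag(sv$d[seq_len(n_components)], n_components),
                  2, flip, `*`)
  loadings <- sweep(sv$v[, seq_len(n_components), drop = FALSE], 2, flip, `*`)
  dimnames(scores) <- list(rownames(X), paste0("PC", seq_len(n_components)))
  dimnames(loadings) <- list(colnames(X), paste0("PC", seq_len(n_components)))
  list(scores = scores, loadings = loadings,
       sdev = sv$d[seq_len(n_components)] / sqrt(max(1, nrow(X) - 1)),
       center = ctr)
}
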