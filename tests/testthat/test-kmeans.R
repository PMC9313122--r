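test_that("edge cases: one cluster and one cluster per point", {
  set.seed(42)
  X <- matrix(rnorm(24), 8, 3)
  r1 <- hartigan_wong(X, k = 1, seed = 1)
  expect_equal(as.numeric(r1$centers), colMeans(X))
  expect_equal(r1$wcss, sum(sweep(X, 2, colMeans(X))^2))
  rn <- hartigan_wong(X, k = nrow(X), seed = 1)
  expect_equal(rn$wcss, 0)
  expect_equal(sort(unique(rn$assignments)), 1:8)
  expect_error(hartigan_wong(X, k = 9), "between 1 and")
})

test_that("solutions match exhaustive partition search on small fixtures", {
  for (seed in 1:4) {
    set.seed(seed)
    X <- matrix(rnorm(14), 7, 2)
    for (k in 2:3) {
      res <- hartigan_wong(X, k = k, n_restarts = 30, seed = seed)
      expect_equal(res$wcss, brute_force_wcss(X, k), tolerance = 1e-8)
    }
  }
})

test_that("wcss is internally consistent and monotone in k", {
  set.seed(5)
  X <- matrix(rnorm(60), 20, 3)
  prev <- Inf
  for (k in 1:5) {
    res <- hartigan_wong(X, k = k, n_restarts = 30, seed = 7)
    recomputed <- sum(vapply(seq_len(nrow(X)), function(i)
      sum((X[i, ] - res$centers[res$assignments[i], ])^2), numeric(1)))
    expect_equal(res$wcss, recomputed, tolerance = 1e-10)
    expect_lte(res$wcss, prev + 1e-10)
    prev <- res$wcss
    expect_equal(sort(unique(res$assignments)), seq_len(k))  # no empty cluster
  }
})

test_that("a far outlier becomes a singleton cluster at k = 5", {
  set.seed(8)
  blobs <- do.call(rbind, lapply(1:4, function(b)
    matrix(rnorm(16, mean = 6 * b, sd = 0.2), 8, 2)))
  outlier <- matrix(c(-50, -50), 1, 2)
  X <- rbind(blobs, outlier)
  rownames(X) <- c(sprintf("A%02d", 1:32), "OUTLIER")
  res <- cluster_avatars(X, k_candidates = c(4, 5), n_restarts = 30, seed = 2)
  expect_identical(res$k5$singletons, "OUTLIER")
  # duplicated rows always share a cluster
  Xd <- rbind(X, X["A01", , drop = FALSE])
  rd <- hartigan_wong(Xd, k = 4, n_restarts = 30, seed = 2)
  expect_equal(rd$assignments[33 + 1], rd$assignments["A01"],
               ignore_attr = TRUE)
})

test_that("row permutation and reruns leave the partition unchanged", {
  set.seed(9)
  X <- rbind(matrix(rnorm(20, 0, 0.3), 10, 2),
             matrix(rnorm(20, 5, 0.3), 10, 2),
             matrix(rnorm(16, c(0, 8), 0.3), 8, 2))
  rownames(X) <- sprintf("R%02d", seq_len(nrow(X)))
  r1 <- hartigan_wong(X, k = 3, n_restarts = 25, seed = 4)
  r2 <- hartigan_wong(X, k = 3, n_restarts = 25, seed = 4)
  expect_identical(r1$assignments, r2$assignments)  # same-seed determinism
  perm <- sample(nrow(X))
  rp <- hartigan_wong(X[perm, ], k = 3, n_restarts = 25, seed = 4)
  # same partition as sets of row names, up to cluster relabeling
  part <- function(a) unname(sort(vapply(split(names(a), a), function(s)
    paste(sort(s), collapse = ","), character(1))))
  expect_identical(part(rp$assignments), part(r1$assignments))
})

test_that("pca projection is an ordered, sign-fixed SVD of the centered data", {
  set.seed(10)
  X <- matrix(rnorm(40), 10, 4)
  p <- pca_project(X, n_components = 4)
  vars <- apply(p$scores, 2, var)
  expect_true(all(diff(vars) <= 1e-10))
  # full-rank reconstruction returns the centered matrix
  expect_equal(p$scores %*% t(p$loadings), sweep(X, 2, colMeans(X)),
               tolerance = 1e-10)
  # 1-D data embedded in 2 columns: second component is numerically null
  t1 <- rnorm(10)
  X1 <- cbind(t1, 2 * t1)
  p1 <- pca_project(X1)
  expect_lt(var(p1$scores[, 2]), 1e-20)
  expect_message(pc <- pca_project(matrix(1, 5, 2)), "constant")
  expect_true(all(pc$scores == 0))
})
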