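# Landmark subsampling, bipartite kNN graph, k-means++, bipartite
# modularity, and parallel reassignment.

test_that("landmark subsampling is uniform, capped and deterministic", {
  X <- matrix(rnorm(200), 100, 2)
  expect_identical(subsample_landmarks(X, 25000), 1:100)
  big <- matrix(0, 60000, 1)
  lm1 <- subsample_landmarks(big, 25000, seed = 3)
  lm2 <- subsample_landmarks(big, 25000, seed = 3)
  expect_identical(lm1, lm2)
  expect_length(lm1, 25000)
  expect_false(identical(lm1, subsample_landmarks(big, 25000, seed = 4)))
})

test_that("kNN bipartite graph agrees with a brute-force oracle", {
  set.seed(1)
  X <- matrix(rnorm(500 * 3), 500, 3)
  lm <- subsample_landmarks(X, 200, seed = 1)
  g <- knn_bipartite(X, lm, k = 7)
  # every left node has degree exactly k
  expect_true(all(Matrix::rowSums(g$A) == 7))
  expect_equal(g$m, 500 * 7)
  # oracle: full distance matrix, ties by landmark index
  D <- as.matrix(dist(rbind(X)))[, lm]
  for (i in c(1, 57, 499)) {
    oracle <- order(D[i, ], seq_along(lm))[1:7]
    expect_setequal(g$nn[i, ], oracle)
  }
  expect_error(knn_bipartite(cbind(c(1, NaN)), 1:2, 1), "non-finite")
})

test_that("separated blobs share no cross-blob edges", {
  set.seed(2)
  X <- rbind(matrix(rnorm(600, 0, 0.5), ncol = 2),
             matrix(rnorm(600, 20, 0.5), ncol = 2))
  lm <- subsample_landmarks(X, 200, seed = 1)
  g <- knn_bipartite(X, lm, k = 5)
  side <- rep(1:2, each = 300)
  lm_side <- side[lm]
  for (i in seq_len(nrow(X)))
    expect_true(all(lm_side[g$nn[i, ]] == side[i]))
})

test_that("k-means++ init is deterministic and blob-pure", {
  set.seed(3)
  X <- rbind(matrix(rnorm(900, 0), ncol = 3),
             matrix(rnorm(900, 12), ncol = 3),
             matrix(rnorm(900, 24), ncol = 3))
  a <- kmeanspp_init(X, 200, seed = 5)
  b <- kmeanspp_init(X, 200, seed = 5)
  expect_identical(a, b)
  blob <- rep(1:3, each = 300)
  expect_true(all(rowSums(table(a, blob) > 0) == 1)) # no cluster spans blobs
  # N == n_init: every point its own cluster
  small <- matrix(rnorm(20), 10, 2)
  expect_setequal(kmeanspp_init(small, 10, seed = 1), 1:10)
})

test_that("bipartite modularity matches hand values and a summation oracle", {
  # complete bipartite graph on 4 points, all landmarks, k = 4:
  # one cluster has e_c = m, K_left = K_right = m, so H = 1/2 - gamma/4
  X <- matrix(c(0, 0, 0, 0, 1, 2, 3, 4), 4, 2)
  g <- knn_bipartite(X, 1:4, k = 4)
  expect_equal(bipartite_modularity(g, rep(1L, 4), rep(1L, 4)), 0.25)
  expect_equal(bipartite_modularity(g, rep(1L, 4), rep(1L, 4), gamma = 2),
               0)
  # empty graph convention
  g0 <- g; g0$m <- 0
  expect_equal(bipartite_modularity(g0, rep(1L, 4), rep(1L, 4)), 0)
  # random small graphs vs explicit edge-list summation
  set.seed(6)
  for (rep in 1:5) {
    Y <- matrix(rnorm(40), 20, 2)
    gg <- knn_bipartite(Y, sort(sample(20, 8)), k = 3)
    ll <- sample(3L, 20, replace = TRUE)
    lr <- sample(3L, 8, replace = TRUE)
    # oracle: iterate explicit edges
    ec <- numeric(3); kl <- numeric(3); kr <- numeric(3)
    for (i in 1:20) for (q in 1:3) {
      j <- gg$nn[i, q]
      if (ll[i] == lr[j]) ec[ll[i]] <- ec[ll[i]] + 1
    }
    for (i in 1:20) kl[ll[i]] <- kl[ll[i]] + gg$k_left[i]
    for (j in 1:8) kr[lr[j]] <- kr[lr[j]] + gg$k_right[j]
    H_oracle <- sum(ec - kl * kr / (2 * gg$m)) / (2 * gg$m)
    expect_equal(bipartite_modularity(gg, ll, lr), H_oracle)
  }
})

test_that("reassignment merges disconnected cliques and modularity never decreases", {
  set.seed(7)
  # two tight 12-point blobs with k = 12: each blob is a complete
  # bipartite clique, the blobs are disconnected; init with 4 clusters
  X <- rbind(matrix(rnorm(24, 0, 0.2), ncol = 2),
             matrix(rnorm(24, 30, 0.2), ncol = 2))
  g <- knn_bipartite(X, 1:24, k = 12)
  init <- rep(1:4, each = 6) # two initial clusters per clique
  fit <- iterate_reassignment(g, init)
  expect_identical(fit$n_clusters, 2L)
  expect_true(all(diff(fit$modularity) >= -1e-12))
  tab <- table(fit$labels_left, rep(1:2, each = 12))
  expect_true(all(rowSums(tab > 0) == 1))
  # larger blobs: labels never span blobs and modularity stays monotone
  Y <- rbind(matrix(rnorm(300, 0, 0.3), ncol = 2),
             matrix(rnorm(300, 15, 0.3), ncol = 2))
  g2 <- knn_bipartite(Y, 1:300, k = 8)
  fit2 <- iterate_reassignment(g2, kmeanspp_init(Y, 20, seed = 2))
  expect_true(all(diff(fit2$modularity) >= -1e-12))
  tab2 <- table(fit2$labels_left, rep(1:2, each = 150))
  expect_true(all(rowSums(tab2 > 0) == 1))
})

test_that("small instances reach the exhaustive modularity optimum", {
  # enumerate all partitions of n <= 8 points (Bell numbers) and compare
  set.seed(8)
  partitions_of <- function(n) {
    if (n == 1) return(list(list(1L)))
    out <- list()
    for (p in partitions_of(n - 1)) {
      for (b in seq_along(p)) {
        q <- p; q[[b]] <- c(q[[b]], n)
        out[[length(out) + 1]] <- q
      }
      out[[length(out) + 1]] <- c(p, list(n))
    }
    out
  }
  as_labels <- function(p, n) {
    lab <- integer(n)
    for (b in seq_along(p)) lab[p[[b]]] <- b
    lab
  }
  n <- 8
  parts <- partitions_of(n)
  hits <- 0; trials <- 20
  for (tr in seq_len(trials)) {
    # clusterable layouts: two well-separated blobs of random sizes
    n1 <- sample(3:5, 1)
    X <- rbind(matrix(rnorm(2 * n1, sd = 0.5), n1, 2),
               matrix(rnorm(2 * (n - n1), 8, sd = 0.5), n - n1, 2))
    g <- knn_bipartite(X, 1:n, k = 3)
    best <- max(vapply(parts, function(p) {
      lab <- as_labels(p, n)
      bipartite_modularity(g, lab, lab)
    }, numeric(1)))
    # production-ratio seeding: ~4 points per seed, as with 200 seeds
    # on a full-size section
    fit <- iterate_reassignment(g, kmeanspp_init(X, 2, seed = tr))
    got <- bipartite_modularity(g, fit$labels_left, fit$labels_right)
    if (got >= best - 1e-9) hits <- hits + 1
  }
  expect_gte(hits / trials, 0.9)
})
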