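# Merging tree, bimodality, correlograms, traversal, global merges,
# good-unit labels.

test_that("gamma_hat follows the closed form and merge ordering", {
  # two clusters, k1 = k2 = 10, K12 = 2, 2m = 20 -> gamma_hat = 0.4
  expect_equal(2 * 10 * 2 / (10 * 10), 0.4) # arithmetic anchor
  set.seed(1)
  # construct a graph realizing those aggregates: 10 points, 2 blobs,
  # k = 1 edge each to landmarks, with 2 cross edges
  X <- rbind(matrix(rnorm(10, 0, 0.1), 5, 2), matrix(rnorm(10, 9, 0.1), 5, 2))
  g <- knn_bipartite(X, 1:10, k = 2)
  lab <- rep(1:2, each = 5L)
  tree <- build_merge_tree(g, lab, lab)
  ag <- spikegraph:::aggregate_graph(g, lab, lab)
  expect_equal(tree$nodes$gamma_hat[1],
               2 * ag$m * ag$K[1, 2] / (ag$k[1] * ag$k[2]))
  # three clusters: (1,2) share edges, 3 shares none -> first merge (1,2)
  Y <- rbind(matrix(rnorm(20, 0, 0.4), 10, 2),
             matrix(rnorm(20, 2, 0.4), 10, 2),
             matrix(rnorm(20, 50, 0.4), 10, 2))
  gy <- knn_bipartite(Y, 1:30, k = 3)
  laby <- rep(1:3, each = 10L)
  ty <- build_merge_tree(gy, laby, laby)
  expect_setequal(unlist(ty$nodes[1, c("child1", "child2")]), c(1, 2))
  expect_equal(ty$nodes$gamma_hat[2], 0) # disconnected cluster merges last
})

test_that("gamma_hat is non-increasing toward the root (vs naive re-scan)", {
  set.seed(2)
  for (rep in 1:4) {
    X <- matrix(rnorm(160), 80, 2)
    g <- knn_bipartite(X, sort(sample(80, 40)), k = 4)
    lab <- kmeanspp_init(X, 12, seed = rep)
    lab <- match(lab, sort(unique(lab)))
    tree <- build_merge_tree(g, lab, lab[g$landmarks])
    gh <- tree$nodes$gamma_hat
    expect_true(all(diff(gh) <= 1e-9))
    # naive oracle: recompute the best pair from scratch at step 1
    ag <- spikegraph:::aggregate_graph(g, lab, lab[g$landmarks])
    ghm <- 2 * ag$m * ag$K / outer(ag$k, ag$k)
    diag(ghm) <- -Inf
    expect_equal(gh[1], max(ghm))
  }
})

test_that("bimodality scores separate the canonical cases", {
  set.seed(3)
  # projections near -1/+1: well-separated unit-variance clusters
  f1 <- matrix(rnorm(10000), ncol = 2) +
    matrix(c(3, 0), 5000, 2, byrow = TRUE)
  f2 <- matrix(rnorm(10000), ncol = 2) +
    matrix(c(-3, 0), 5000, 2, byrow = TRUE)
  expect_gt(bimodality_score(f1, f2)$bimod, 0.9)
  # one Gaussian split randomly in half
  g <- matrix(rnorm(16000), ncol = 2)
  expect_lte(bimodality_score(g[1:4000, ], g[4001:8000, ])$bimod, 0.05)
  # histogram mass is conserved by smoothing
  bm <- bimodality_score(f1, f2)
  expect_equal(sum(bm$hist),
               sum(abs(bm$x_proj) <= 2 + 1e-12), tolerance = 1e-9)
  expect_lte(bm$bimod, 1)
})

test_that("correlogram statistics behave on canonical trains", {
  set.seed(4)
  # independent Poisson trains: flat CCG, not refractory
  a <- sort(runif(3000, 0, 600)); b <- sort(runif(3000, 0, 600))
  st <- compute_correlograms(a, b)
  expect_gt(st$R12, 0.5); expect_lt(st$R12, 1.5)
  expect_gt(st$Q12, 0.05)
  expect_false(is_refractory(st, "ccg"))
  # CCG symmetry: counts for (a,b) reverse to (b,a)
  st_ba <- compute_correlograms(b, a)
  expect_equal(st$counts, rev(st_ba$counts))
  # P_k = 0.5 exactly when n_k equals lambda_k (erf(0) = 0)
  erf0 <- spikegraph:::erf(0)
  expect_identical(0.5 * (1 + erf0), 0.5)
  lam <- st$R * (2 * (0:10) + 1)
  Pk <- 0.5 * (1 + spikegraph:::erf((lam - lam) / sqrt(1e-10 + 2 * lam)))
  expect_equal(Pk, rep(0.5, 11))
  # absolute refractory train against itself: empty center
  tr <- fixture_refractory_train(10, 400, seed = 5)
  sa <- compute_correlograms(tr, tr)
  expect_identical(sa$n_k[1], 0)
  expect_identical(sa$R12, 0)
  expect_true(is_refractory(sa, "acg"))
  # too few spikes: flagged, conservative
  tiny <- compute_correlograms(1.0, c(0.5, 2))
  expect_true(tiny$insufficient)
  expect_false(is_refractory(tiny, "ccg"))
})

test_that("refractoriness thresholds apply per mode", {
  mk <- function(R12, Q12) structure(list(R12 = R12, Q12 = Q12,
                                          insufficient = FALSE),
                                     class = "correlogram_stats")
  expect_true(is_refractory(mk(0.2, 0.01), "ccg"))
  expect_false(is_refractory(mk(0.2, 0.01), "acg")) # R12 >= 0.1
  expect_false(is_refractory(mk(0.3, 0.01), "ccg"))
  expect_false(is_refractory(mk(0.2, 0.06), "ccg"))
  expect_true(is_refractory(mk(0.05, 0.1), "acg"))
})

test_that("tree traversal re-merges a randomly halved unit and splits real pairs", {
  set.seed(6)
  # one unit's feature cloud + refractory train, halved at random
  n <- 4000
  X <- matrix(rnorm(2 * n, sd = 1), n, 2)
  tr <- fixture_refractory_train(12, 600, seed = 7)[1:n]
  half <- sample(rep(1:2, length.out = n))
  cl <- cluster_features(X, n_sub = 1500, k = 8, n_init = 40, seed = 1)
  # force leaves to be the two halves for a controlled tree
  g <- cl$graph
  tree <- build_merge_tree(g, half, half[g$landmarks])
  tv <- traverse_tree(tree, X, half, spike_times = tr)
  expect_identical(max(tv$labels), 1L) # merged back into one unit
  # two independent units with distinct means: bimodal, kept split
  X2 <- rbind(matrix(rnorm(2 * n, sd = 1), n, 2) + 5, X)
  tr2 <- c(fixture_refractory_train(12, 600, seed = 8)[1:n] + 0.0005, tr)
  lab2 <- rep(1:2, each = n)
  ord <- order(tr2)
  g2 <- knn_bipartite(X2, sort(sample(2 * n, 1500)), k = 8)
  tree2 <- build_merge_tree(g2, lab2, lab2[g2$landmarks])
  tv2 <- traverse_tree(tree2, X2, lab2, spike_times = tr2)
  expect_identical(max(tv2$labels), 2L)
  tab <- table(tv2$labels, lab2)
  expect_true(all(rowSums(tab > 0) == 1))
})

test_that("a refractory CCG keeps a duplicated-unit pair merged", {
  set.seed(9)
  # same neuron's spikes divided between two clusters whose features also
  # differ (waveform nonstationarity): bimodal, but the CCG is refractory.
  # Two unrelated neighboring units provide the section's remaining mass.
  n <- 3000
  tr <- fixture_refractory_train(10, 600, seed = 10)[1:n]
  half <- rep(1:2, length.out = n) # alternating spikes
  X <- matrix(rnorm(2 * n), n, 2) + cbind(ifelse(half == 1, 2, -2), 0)
  centers <- rbind(c(12, 0), c(-12, 12), c(0, -14), c(14, 14))
  Xo <- do.call(rbind, lapply(1:4, function(i)
    sweep(matrix(rnorm(2 * n), n, 2), 2, centers[i, ], "+")))
  to <- unlist(lapply(1:4, function(i) sort(runif(n, 0, 600))))
  lab <- c(half, rep(3:6, each = n))
  Xall <- rbind(X, Xo)
  times <- c(tr, to)
  g <- knn_bipartite(Xall, sort(sample(5 * n, 8000)), k = 8)
  tree <- build_merge_tree(g, lab, lab[g$landmarks])
  # bimodality alone would split the pair
  expect_gt(bimodality_score(X[half == 1, ], X[half == 2, ])$bimod, 0.5)
  tv <- traverse_tree(tree, Xall, lab, spike_times = times)
  # halves rescued by the refractory CCG; unrelated units stay apart
  expect_identical(max(tv$labels), 5L)
  expect_identical(length(unique(tv$labels[lab <= 2])), 1L)
})

test_that("global merges join boundary-straddling units only when refractory", {
  set.seed(11)
  geom <- probe_linear(16)
  tr <- fixture_refractory_train(12, 600, seed = 12)
  half <- rep(1:2, length.out = length(tr))
  W <- fixture_template(geom, 8)
  shifted <- rbind(W[-1, ], 0) # one-pitch shifted copy: high similarity
  units <- list(
    list(times = tr[half == 1], waveform = 12 * W),
    list(times = tr[half == 2], waveform = 12 * shifted),
    list(times = fixture_refractory_train(8, 600, seed = 13),
         waveform = 10 * fixture_template(geom, 3)))
  expect_gt(waveform_similarity(units[[1]]$waveform, units[[2]]$waveform),
            0.5)
  gm <- global_merges(units)
  expect_identical(gm$assignment[1], gm$assignment[2]) # same neuron joined
  expect_false(gm$assignment[3] == gm$assignment[1])   # independent stays
  # unit with no candidate above 0.5 is untouched
  expect_length(gm$units, 2)
})

test_that("good/mua labels follow the ACG contamination rule", {
  tr <- fixture_refractory_train(12, 600, seed = 14)
  expect_identical(label_good(tr), "good")
  set.seed(15)
  pois <- sort(runif(7000, 0, 600)) # no refractory structure
  expect_identical(label_good(pois), "mua")
  # 90/10 mixture with an independent contaminant
  mix <- sort(c(tr, sort(runif(round(length(tr) * 0.35), 0, 600))))
  expect_identical(label_good(mix), "mua")
  expect_identical(label_good(c(0.1)), "mua") # insufficient spikes
})
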