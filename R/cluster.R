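# Landmark-based bipartite modularity clustering.
#
# All points are "left" nodes; a uniformly subsampled set of landmark
# copies forms the "right" nodes; edges run only left -> right (each point
# to its k nearest landmarks). Because the graph is bipartite, all left
# labels can be updated in parallel given the right labels and vice versa,
# which is what makes the sweep embarrassingly parallel.

#' Subsample landmark points
#'
#' @param features N x d matrix.
#' @param n_sub Number of landmarks (default 25,000 for a 40-um probe
#'   section).
#' @param seed RNG seed.
#' @return Integer vector of landmark row indices (sorted).
#' @export
subsample_landmarks <- function(features, n_sub = 25000, seed = 1) {
  N <- nrow(features)
  if (N <= n_sub) return(seq_len(N))
  set.seed(seed)
  sort(sample.int(N, n_sub))
}

#' Exact k-nearest-landmark bipartite graph
#'
#' Brute-force Euclidean k-nearest landmarks for every point (ties broken
#' by landmark index).
#'
#' @param features N x d matrix.
#' @param landmarks Indices into rows of `features` (the right nodes).
#' @param k Neighbors per point (default 10).
#' @return A `bipartite_graph`: `nn` (N x k landmark-copy indices), sparse
#'   adjacency `A` (N x L), degrees `k_left`, `k_right`, total edges `m`,
#'   plus `features` and `landmarks`.
#' @export
knn_bipartite <- function(features, landmarks, k = 10) {
  features <- as.matrix(features)
  if (any(!is.finite(features))) stop("non-finite features")
  L <- length(landmarks)
  k <- min(k, L)
  nn <- cpp_knn(features, features[landmarks, , drop = FALSE], k)
  N <- nrow(features)
  A <- Matrix::sparseMatrix(i = rep(seq_len(N), k), j = as.vector(nn),
                            x = 1, dims = c(N, L))
  structure(list(nn = nn, A = A, k = k, m = N * k,
                 k_left = rep(k, N), k_right = Matrix::colSums(A),
                 landmarks = landmarks, features = features),
            class = "bipartite_graph")
}

#' k-means++ initialization
#'
#' Standard D^2-weighted seeding followed by assignment of every point to
#' its nearest seed.
#'
#' @param features N x d matrix.
#' @param n_init Number of seeds (default 200; capped at N).
#' @param seed RNG seed.
#' @return Integer labels in 1..n_init.
#' @export
kmeanspp_init <- function(features, n_init = 200, seed = 1) {
  features <- as.matrix(features)
  N <- nrow(features)
  n_init <- min(n_init, N)
  set.seed(seed)
  centers <- integer(n_init)
  centers[1] <- sample.int(N, 1)
  d2 <- rowSums(sweep(features, 2, features[centers[1], ])^2)
  if (n_init > 1) for (i in 2:n_init) {
    if (sum(d2) == 0) {
      centers[i] <- sample.int(N, 1)
    } else {
      centers[i] <- sample.int(N, 1, prob = d2)
    }
    nd <- rowSums(sweep(features, 2, features[centers[i], ])^2)
    d2 <- pmin(d2, nd)
  }
  nn <- cpp_knn(features, features[centers, , drop = FALSE], 1)
  as.integer(nn[, 1])
}

cluster_sizes_ok <- function(labels) all(tabulate(labels) > 0)

# indicator matrix (n x C) for integer labels 1..C
label_ind <- function(labels, C) {
  Matrix::sparseMatrix(i = seq_along(labels), j = labels, x = 1,
                       dims = c(length(labels), C))
}

#' Bipartite modularity
#'
#' `H = (1/2m) * sum_c (e_c - gamma * K_c_left * K_c_right / (2m))` where
#' `e_c` counts edges with both endpoints in cluster `c` and `K_c_left`,
#' `K_c_right` are the summed left/right degrees in `c`.
#'
#' @param graph A `bipartite_graph`.
#' @param labels_left,labels_right Integer labels for points and landmark
#'   copies.
#' @param gamma Resolution parameter (default 1).
#' @export
bipartite_modularity <- function(graph, labels_left, labels_right,
                                 gamma = 1) {
  m <- graph$m
  if (m == 0) return(0)
  C <- max(labels_left, labels_right)
  Kl <- as.vector(Matrix::crossprod(label_ind(labels_left, C),
                                    graph$k_left))
  Kr <- as.vector(Matrix::crossprod(label_ind(labels_right, C),
                                    graph$k_right))
  ntc <- graph$A %*% label_ind(labels_right, C) # N x C neighbor counts
  ec <- sum(ntc[cbind(seq_len(nrow(ntc)), labels_left)])
  (ec - gamma * sum(Kl * Kr) / (2 * m)) / (2 * m)
}

#' Iterative parallel reassignment to a modularity local minimum
#'
#' Alternates synchronous sweeps: every left node is reassigned in parallel
#' to `argmax_c (n_tc - gamma * k_t * K_c_right / 2m)` given fixed right
#' labels, then every right node symmetrically. Ties go to the lowest
#' cluster id, so runs are bit-reproducible. Sweeps stop when no label
#' changes or after `n_iter` sweeps; empty clusters are dropped. The
#' resulting partition is a local minimum, biased toward oversplitting --
#' merges are handled later by the merging tree.
#'
#' @param graph A `bipartite_graph`.
#' @param init Initial labels for all points (left nodes); right copies
#'   inherit their point's label.
#' @param gamma Resolution (default 1).
#' @param n_iter Maximum sweeps (default 30).
#' @param sequential Update one node at a time with immediately refreshed
#'   aggregates instead of synchronous parallel sweeps. Slower, but able to
#'   dissolve frozen sub-clusters; used as the reference optimizer in
#'   small-instance oracle checks.
#' @return List with `labels_left`, `labels_right`, `n_clusters`,
#'   `modularity` (per-sweep trace), `converged`.
#' @export
iterate_reassignment <- function(graph, init, gamma = 1, n_iter = 30,
                                 sequential = FALSE) {
  if (sequential)
    return(iterate_reassignment_seq(graph, init, gamma, n_iter))
  ll <- as.integer(init)
  lr <- ll[graph$landmarks]
  relabel <- function() {
    keep <- sort(unique(c(ll, lr)))
    map <- integer(max(keep)); map[keep] <- seq_along(keep)
    ll <<- map[ll]; lr <<- map[lr]
    length(keep)
  }
  C <- relabel()
  m <- graph$m
  At <- Matrix::t(graph$A)
  htrace <- bipartite_modularity(graph, ll, lr, gamma)
  converged <- FALSE
  for (it in seq_len(n_iter)) {
    old_ll <- ll; old_lr <- lr
    # left sweep
    Kr <- as.vector(Matrix::crossprod(label_ind(lr, C), graph$k_right))
    ntc <- as.matrix(graph$A %*% label_ind(lr, C))
    score <- ntc - (gamma / (2 * m)) * outer(graph$k_left, Kr)
    ll <- max.col(score, ties.method = "first")
    # right sweep
    Kl <- as.vector(Matrix::crossprod(label_ind(ll, C), graph$k_left))
    nrc <- as.matrix(At %*% label_ind(ll, C))
    score <- nrc - (gamma / (2 * m)) * outer(graph$k_right, Kl)
    lr <- max.col(score, ties.method = "first")
    C <- relabel()
    htrace <- c(htrace, bipartite_modularity(graph, ll, lr, gamma))
    if (identical(ll, old_ll) && identical(lr, old_lr)) {
      converged <- TRUE
      break
    }
  }
  list(labels_left = ll, labels_right = lr, n_clusters = C,
       modularity = htrace, converged = converged)
}

#' Cluster a feature matrix end to end
#'
#' Landmark subsampling, exact kNN bipartite graph, k-means++
#' initialization with `n_init` clusters, and iterative parallel
#' reassignment.
#'
#' @param features N x d matrix.
#' @param n_sub Landmark budget (default 25,000).
#' @param k Neighbors per point (default 10).
#' @param n_init k-means++ seeds (default 200).
#' @param gamma,n_iter Passed to [iterate_reassignment()].
#' @param seed RNG seed.
#' @return List with `labels` (left labels per point), `graph`, `fit`.
#' @export
cluster_features <- function(features, n_sub = 25000, k = 10, n_init = 200,
                             gamma = 1, n_iter = 30, seed = 1) {
  features <- as.matrix(features)
  lm <- subsample_landmarks(features, n_sub, seed = seed)
  graph <- knn_bipartite(features, lm, k)
  init <- kmeanspp_init(features, n_init, seed = seed)
  fit <- iterate_reassignment(graph, init, gamma, n_iter)
  list(labels = fit$labels_left, graph = graph, fit = fit)
}


# Sequential single-node reassignment: each move immediately updates the
# cluster aggregates, letting chains of boundary moves dissolve frozen
# sub-clusters that the synchronous sweeps cannot merge.
iterate_reassignment_seq <- function(graph, init, gamma = 1, n_iter = 100) {
  ll <- as.integer(init)
  lr <- ll[graph$landmarks]
  keep <- sort(unique(c(ll, lr)))
  map <- integer(max(keep)); map[keep] <- seq_along(keep)
  ll <- map[ll]; lr <- map[lr]
  C <- length(keep)
  m <- graph$m
  kr <- graph$k_right
  htrace <- bipartite_modularity(graph, ll, lr, gamma)
  converged <- FALSE
  for (it in seq_len(n_iter)) {
    changed <- FALSE
    Kr <- as.vector(Matrix::crossprod(label_ind(lr, C), kr))
    for (t in seq_len(nrow(graph$nn))) {
      ntc <- tabulate(lr[graph$nn[t, ]], nbins = C)
      score <- ntc - (gamma / (2 * m)) * graph$k_left[t] * Kr
      new <- which.max(score)
      if (new != ll[t]) { ll[t] <- new; changed <- TRUE }
    }
    Kl <- as.vector(Matrix::crossprod(label_ind(ll, C), graph$k_left))
    for (r in seq_len(length(lr))) {
      # neighbors of right node r = left nodes with an edge to r
      nb <- which(graph$A[, r] > 0)
      nrc <- tabulate(ll[nb], nbins = C)
      score <- nrc - (gamma / (2 * m)) * kr[r] * Kl
      new <- which.max(score)
      if (new != lr[r]) {
        Kr[lr[r]] <- Kr[lr[r]] - kr[r]
        Kr[new] <- Kr[new] + kr[r]
        lr[r] <- new
        changed <- TRUE
      }
    }
    htrace <- c(htrace, bipartite_modularity(graph, ll, lr, gamma))
    if (!changed) { converged <- TRUE; break }
  }
  keep <- sort(unique(c(ll, lr)))
  map <- integer(max(keep)); map[keep] <- seq_along(keep)
  list(labels_left = map[ll], labels_right = map[lr],
       n_clusters = length(keep), modularity = htrace,
       converged = converged)
}
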