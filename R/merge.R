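# Merging tree over local-minimum clusters, and the curation criteria used
# to traverse it: projection bimodality and correlogram refractoriness.

# Aggregate the bipartite graph into cluster-level edge counts K (C x C,
# K_ij = edges between clusters, K_ii = internal edges) and degrees k_i.
aggregate_graph <- function(graph, labels_left, labels_right) {
  C <- max(labels_left, labels_right)
  Il <- label_ind(labels_left, C)
  Ir <- label_ind(labels_right, C)
  E <- as.matrix(Matrix::t(Il) %*% graph$A %*% Ir) # directed left->right
  K <- E + t(E)
  diag(K) <- diag(E) # count internal edges once
  k <- as.vector(Matrix::crossprod(Il, graph$k_left)) +
    as.vector(Matrix::crossprod(Ir, graph$k_right))
  list(K = K, k = k, m = graph$m, C = C)
}

#' Build the hierarchical merging tree
#'
#' Starting from the leaf clusters, repeatedly merges the pair with the
#' largest `gamma_hat_ij = 2 m K_ij / (k_i k_j)` -- the resolution value at
#' which merging clusters i and j stops changing the modularity --
#' re-aggregating counts after every merge until a single root remains.
#' Disconnected pairs (`K_ij = 0`) have `gamma_hat = 0` and merge last in
#' deterministic index order. The recorded `gamma_hat` values are
#' non-increasing from leaves to root.
#'
#' @param graph A `bipartite_graph`.
#' @param labels_left,labels_right Leaf cluster labels from
#'   [iterate_reassignment()].
#' @return A `merge_tree`: tibble `nodes` with one row per internal node
#'   (`child1`, `child2`, `gamma_hat`, `K_ij`, `k_i`, `k_j`, `id`), plus
#'   `n_leaves`, `m`, and `leaves` (list of leaf sets per node id).
#' @export
build_merge_tree <- function(graph, labels_left,
                             labels_right = labels_left[graph$landmarks]) {
  ag <- aggregate_graph(graph, labels_left, labels_right)
  K <- ag$K; k <- ag$k; m <- ag$m; C <- ag$C
  active <- seq_len(C)
  ids <- seq_len(C) # current node id per active cluster
  leaves <- as.list(seq_len(C))
  nodes <- list()
  nid <- C
  while (length(active) > 1) {
    n <- length(active)
    gh <- 2 * m * K / outer(k, k)
    diag(gh) <- -Inf
    best <- which(gh == max(gh), arr.ind = TRUE)
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    i <- min(best); j <- max(best)
    nid <- nid + 1
    nodes[[length(nodes) + 1]] <- tibble::tibble(
      id = nid, child1 = ids[i], child2 = ids[j],
      gamma_hat = gh[i, j], K_ij = K[i, j], k_i = k[i], k_j = k[j])
    leaves[[nid]] <- c(leaves[[ids[i]]], leaves[[ids[j]]])
    # aggregate cluster j into i: internal edges K_ii + K_jj + K_ij
    Kij <- K[i, j]
    K[i, ] <- K[i, ] + K[j, ]
    K[, i] <- K[, i] + K[, j]
    K[i, i] <- K[i, i] - Kij # row+col both added the cross edges
    k[i] <- k[i] + k[j]
    ids[i] <- nid
    K <- K[-j, -j, drop = FALSE]
    k <- k[-j]
    ids <- ids[-j]
    active <- active[-1]
  }
  structure(list(nodes = dplyr::bind_rows(nodes), n_leaves = C, m = m,
                 leaves = leaves),
            class = "merge_tree")
}

#' @export
print.merge_tree <- function(x, ...) {
  cat(sprintf("<merge_tree> %d leaves, %d merges, gamma_hat root %.3g\n",
              x$n_leaves, nrow(x$nodes),
              if (nrow(x$nodes)) x$nodes$gamma_hat[nrow(x$nodes)] else NA))
  invisible(x)
}

#' Bimodality of the regression-axis projection
#'
#' Fits the weighted least-squares axis `u` predicting labels -1/+1 from
#' features (weights `w_-1 = n2/(n1+n2)`, `w_+1 = n1/(n1+n2)` to balance
#' unequal cluster sizes), projects all points on `u`, histograms the
#' projections in 400 bins on [-2, 2], Gaussian-smooths with an s.d. of 4
#' bins (reflective edges, mass-conserving), finds the trough in the
#' central bins 175-225 and the flanking peaks, and scores
#' `bimod = 1 - max(x_min/x_1, x_min/x_2)`.
#'
#' @param features_i,features_j Feature matrices of the two clusters
#'   (columns aligned).
#' @return A `bimodality_result` list: `u`, `x_proj`, `hist`, `i_min`,
#'   `x_min`, `x_peaks`, `bimod`.
#' @export
bimodality_score <- function(features_i, features_j) {
  features_i <- as.matrix(features_i); features_j <- as.matrix(features_j)
  n1 <- nrow(features_i); n2 <- nrow(features_j)
  stopifnot(n1 > 0, n2 > 0)
  X <- rbind(features_i, features_j)
  y <- c(rep(-1, n1), rep(1, n2))
  w <- ifelse(y < 0, n2, n1) / (n1 + n2)
  XtWX <- crossprod(X, w * X)
  XtWy <- crossprod(X, w * y)
  u <- tryCatch(solve(XtWX, XtWy), error = function(e) {
    lam <- 1e-6 * sum(diag(XtWX))
    solve(XtWX + diag(lam, ncol(X)), XtWy)
  })
  xp <- as.vector(X %*% u)
  br <- seq(-2, 2, length.out = 401)
  h <- tabulate(findInterval(xp, br, rightmost.closed = TRUE,
                             all.inside = FALSE), nbins = 401)[1:400]
  hs <- gauss_smooth(h, 4)
  ctr <- 176:225
  i_min <- ctr[which.min(hs[ctr])]
  # densities below numerical smoothing residue count as empty
  tol <- 1e-9 * sum(hs)
  x_min <- hs[i_min] * (hs[i_min] > tol)
  x1 <- if (i_min > 1) max(hs[1:(i_min - 1)]) else 0
  x2 <- if (i_min < 400) max(hs[(i_min + 1):400]) else 0
  x1 <- x1 * (x1 > tol); x2 <- x2 * (x2 > tol)
  ratio <- function(pk) {
    if (x_min == 0 && pk == 0) 1       # that side holds no mass: unimodal
    else if (pk == 0) Inf
    else x_min / pk
  }
  r1 <- ratio(x1); r2 <- ratio(x2)
  structure(list(u = as.vector(u), x_proj = xp, hist = hs, i_min = i_min,
                 x_min = x_min, x_peaks = c(x1, x2),
                 bimod = 1 - max(r1, r2)),
            class = "bimodality_result")
}

#' Auto-/cross-correlogram refractoriness statistics
#'
#' Bins spike-time differences in 1-ms bins over [-0.5, 0.5] s (for an ACG,
#' zero-lag self pairs are excluded). `n_k` is the count in the central
#' `-k..k` bins (k = 0..`k_max`); the shoulder rate `R` is the larger of
#' the mean counts over the left and right shoulders (|dt| in [50, 500]
#' ms); `R12 = min_k n_k / ((2k+1) R)` and `Q12 = min_k P_k` with the
#' Gaussian-approximated Poisson lower-tail
#' `P_k = (1 + erf((n_k - lambda_k) / sqrt(eps + 2 lambda_k))) / 2`,
#' `lambda_k = (2k+1) R`, `eps = 1e-10`.
#'
#' @param times_a,times_b Sorted spike times in seconds. Equal (identical)
#'   inputs give the ACG.
#' @param k_max Largest central half-width considered (default 10 bins).
#' @param bin_s Bin width, seconds (default 1e-3).
#' @param censor_bins Central bins (per side) excluded from the
#'   refractory statistics. Matching pursuit cannot emit two spikes of
#'   similar templates closer than its exclusion window, so for
#'   deconvolved trains those bins are censored rather than evidence of
#'   refractoriness (default 0: the raw definition).
#' @return A `correlogram_stats` list: `counts`, `n_k`, `R`, `R12`, `Q12`,
#'   `P_k`, `insufficient`.
#' @export
compute_correlograms <- function(times_a, times_b = times_a, k_max = 10,
                                 bin_s = 1e-3, censor_bins = 0) {
  acg <- isTRUE(all.equal(times_a, times_b)) &&
    length(times_a) == length(times_b)
  insufficient <- length(times_a) < 2 || length(times_b) < 2
  nb <- round(0.5 / bin_s)
  counts <- cpp_correlogram(sort(times_a), sort(times_b), bin_s, nb, acg)
  ctr <- nb + 1 # zero-lag bin
  ks <- censor_bins:k_max
  if (censor_bins == 0) {
    n_k <- vapply(ks, function(k) sum(counts[(ctr - k):(ctr + k)]),
                  numeric(1))
    nbins <- 2 * ks + 1
  } else {
    # deconvolved spike trains cannot contain coincidences closer than the
    # extraction's exclusion window; those central bins carry no evidence
    # and are excluded from the refractory statistics
    n_k <- vapply(ks, function(k)
      sum(counts[(ctr - k):(ctr - censor_bins - 1)]) +
        sum(counts[(ctr + censor_bins + 1):(ctr + k)]), numeric(1))
    nbins <- 2 * (ks - censor_bins)
    keep <- nbins > 0
    n_k <- n_k[keep]; nbins <- nbins[keep]; ks <- ks[keep]
  }
  sh_lo <- round(0.05 / bin_s)
  left <- mean(counts[1:(ctr - sh_lo)])
  right <- mean(counts[(ctr + sh_lo):(2 * nb + 1)])
  R <- max(left, right)
  lam <- nbins * R
  R12 <- if (R > 0) min(n_k / lam) else if (all(n_k == 0)) 0 else Inf
  eps <- 1e-10
  P_k <- 0.5 * (1 + erf((n_k - lam) / sqrt(eps + 2 * lam)))
  structure(list(counts = counts, n_k = n_k, R = R, R12 = R12,
                 Q12 = min(P_k), P_k = P_k, k_max = k_max,
                 censor_bins = censor_bins,
                 insufficient = insufficient),
            class = "correlogram_stats")
}

erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Is a correlogram refractory?
#'
#' Both criteria must hold: `R12 < 0.25` and `Q12 < 0.05` for a CCG;
#' `R12 < 0.1` and `Q12 < 0.2` for an ACG. Insufficient spike counts give
#' `FALSE` (conservative).
#'
#' @param stats A `correlogram_stats`.
#' @param mode `"ccg"` or `"acg"`.
#' @export
is_refractory <- function(stats, mode = c("ccg", "acg")) {
  mode <- match.arg(mode)
  if (isTRUE(stats$insufficient)) return(FALSE)
  if (mode == "ccg") stats$R12 < 0.25 && stats$Q12 < 0.05
  else stats$R12 < 0.1 && stats$Q12 < 0.2
}

#' Traverse the merging tree and decide every split
#'
#' Walks the tree from the root down. At each node the two candidate
#' sub-clusters are compared: if their merge gain `K_ij / m` is below
#' `modularity_threshold` the split is always accepted; otherwise a
#' refractory cross-correlogram keeps the node merged (a refractory CCG is
#' the signature of one neuron's spikes having been divided); otherwise the
#' node is split if and only if the regression-axis projection is bimodal
#' (`bimod > bimod_threshold`). When a node is kept merged its subtree is
#' not visited further.
#'
#' @param tree A `merge_tree`.
#' @param features N x d feature matrix for all spikes.
#' @param leaf_labels Leaf cluster label per spike (1..n_leaves).
#' @param spike_times Spike times in seconds.
#' @param bimod_threshold Split when bimod exceeds this (default 0.5).
#' @param modularity_threshold Always split below this merge gain
#'   (default 0.2).
#' @param use_ccg Disable to decide on bimodality alone (used during
#'   template learning).
#' @param fs Unused; times are seconds.
#' @return List with `labels` (final cluster per spike, 1..n_final) and
#'   `audit` (tibble of every decision: node, gamma_hat, bimod, R12, Q12,
#'   decision).
#' @export
traverse_tree <- function(tree, features, leaf_labels, spike_times = NULL,
                          bimod_threshold = 0.5, modularity_threshold = 0.2,
                          use_ccg = TRUE, fs = NULL, censor_bins = 0) {
  features <- as.matrix(features)
  nodes <- tree$nodes
  n_leaves <- tree$n_leaves
  if (!nrow(nodes)) {
    return(list(labels = rep(1L, length(leaf_labels)),
                audit = tibble::tibble()))
  }
  # group id per final cluster: start from root
  audit <- list()
  # recursively decide: returns list of leaf-sets forming final clusters
  decide <- function(id) {
    if (id <= n_leaves) return(list(tree$leaves[[id]]))
    nd <- nodes[nodes$id == id, ]
    lv1 <- tree$leaves[[nd$child1]]
    lv2 <- tree$leaves[[nd$child2]]
    s1 <- which(leaf_labels %in% lv1)
    s2 <- which(leaf_labels %in% lv2)
    gain <- nd$gamma_hat
    bimod <- NA_real_; R12 <- NA_real_; Q12 <- NA_real_
    if (gain < modularity_threshold) {
      decision <- "split:modularity"
    } else {
      refr <- FALSE
      if (use_ccg && !is.null(spike_times)) {
        st <- compute_correlograms(spike_times[s1], spike_times[s2],
                                   censor_bins = censor_bins)
        R12 <- st$R12; Q12 <- st$Q12
        refr <- is_refractory(st, "ccg")
      }
      if (refr) {
        decision <- "merge:refractory"
      } else {
        bm <- bimodality_score(features[s1, , drop = FALSE],
                               features[s2, , drop = FALSE])
        bimod <- bm$bimod
        decision <- if (bimod > bimod_threshold) "split:bimodal"
                    else "merge:unimodal"
      }
    }
    audit[[length(audit) + 1]] <<- tibble::tibble(
      node = nd$id, gamma_hat = nd$gamma_hat, merge_gain = gain,
      bimod = bimod, R12 = R12, Q12 = Q12, decision = decision)
    if (startsWith(decision, "merge")) {
      list(c(lv1, lv2))
    } else {
      c(decide(nd$child1), decide(nd$child2))
    }
  }
  groups <- decide(nodes$id[nrow(nodes)])
  lab <- integer(length(leaf_labels))
  for (g in seq_along(groups)) lab[leaf_labels %in% groups[[g]]] <- g
  list(labels = lab, audit = dplyr::bind_rows(audit))
}

#' Global merges across probe sections
#'
#' After per-section clustering, tests merges across all units. Similarity
#' is the maximum waveform correlation over time lags; units are visited in
#' decreasing spike count, candidates in decreasing similarity (> 0.5), and
#' a merge is performed when the CCG is refractory. A merged unit is
#' retested against all remaining candidates; completed units are removed
#' from future testing.
#'
#' @param units List of units, each with `times` (seconds), `waveform`
#'   (channels x n_t), `n` (spike count).
#' @param sim_threshold Minimum lagged waveform correlation (default 0.5).
#' @return List with `assignment` (new unit id per input unit) and `units`
#'   (merged spike-time lists).
#' @export
global_merges <- function(units, sim_threshold = 0.5, censor_bins = 0) {
  nu <- length(units)
  if (nu == 0) return(list(assignment = integer(0), units = list()))
  parent <- seq_len(nu)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  times <- lapply(units, function(u) sort(u$times))
  wf <- lapply(units, `[[`, "waveform")
  counts <- vapply(times, length, numeric(1))
  completed <- rep(FALSE, nu)
  simfun <- function(i, j) waveform_similarity(wf[[i]], wf[[j]])
  for (i in order(counts, decreasing = TRUE)) {
    if (completed[find(i)]) next
    repeat {
      ri <- find(i)
      roots <- vapply(seq_len(nu), find, integer(1))
      cand <- setdiff(which(!completed & roots == seq_len(nu)), ri)
      if (!length(cand)) break
      sims <- vapply(cand, function(j) simfun(ri, j), numeric(1))
      ord <- cand[order(sims, decreasing = TRUE)]
      sims <- sort(sims, decreasing = TRUE)
      merged_any <- FALSE
      for (q in seq_along(ord)) {
        if (sims[q] <= sim_threshold) break
        j <- ord[q]
        st <- compute_correlograms(times[[ri]], times[[j]],
                                   censor_bins = censor_bins)
        if (is_refractory(st, "ccg")) {
          parent[j] <- ri
          times[[ri]] <- sort(c(times[[ri]], times[[j]]))
          # merged waveform: spike-count weighted average
          w <- counts[ri] / (counts[ri] + counts[j])
          wf[[ri]] <- w * wf[[ri]] + (1 - w) * wf[[j]]
          counts[ri] <- counts[ri] + counts[j]
          merged_any <- TRUE
          break # retest the merged unit against all candidates
        }
      }
      if (!merged_any) break
    }
    completed[find(i)] <- TRUE
  }
  roots <- vapply(seq_len(nu), find, integer(1))
  ids <- match(roots, sort(unique(roots)))
  list(assignment = ids,
       units = lapply(sort(unique(roots)), function(r)
         list(times = times[[r]], waveform = wf[[r]],
              n = length(times[[r]]))))
}

#' Maximum waveform correlation over time lags
#' @param a,b channels x n_t waveform matrices (same dims).
#' @param max_lag Largest lag tested (default half the waveform length).
#' @export
waveform_similarity <- function(a, b, max_lag = floor(ncol(a) / 2)) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  n_t <- ncol(a)
  best <- -Inf
  for (lag in -max_lag:max_lag) {
    ia <- max(1, 1 + lag):min(n_t, n_t + lag)
    ib <- ia - lag
    v <- sum(a[, ia] * b[, ib]) / (na * nb)
    if (v > best) best <- v
  }
  best
}

#' Label a unit good or multi-unit activity
#'
#' A unit is `good` when its ACG contamination estimate `R12` is below the
#' threshold (default 0.2). Units whose expected null coincidence count in
#' the widest central window falls below `min_expected` (too few spikes to
#' measure contamination at all) are `mua`.
#'
#' @param times Spike times, seconds.
#' @param threshold Contamination threshold (default 0.2).
#' @param min_expected Minimum expected coincidences (default 5).
#' @param censor_bins Central ACG bins censored by deconvolution (see
#'   [compute_correlograms()]); without it, any deconvolved train looks
#'   refractory inside the extraction's exclusion window.
#' @export
label_good <- function(times, threshold = 0.2, min_expected = 5,
                       censor_bins = 0) {
  st <- compute_correlograms(times, times, censor_bins = censor_bins)
  # a contamination estimate is only meaningful when contamination would
  # have been observable: require a few expected null coincidences in the
  # widest central window
  if (st$insufficient || (2 * st$k_max + 1) * st$R < min_expected)
    return("mua")
  if (st$R12 < threshold) "good" else "mua"
}
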