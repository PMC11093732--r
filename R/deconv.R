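# Learned spatiotemporal templates and rank-3 matching pursuit.

template_best_channel <- function(W) which.max(rowSums(W^2))

template_position <- function(W, geom) {
  w <- rowSums(W^2)
  c(sum(w * geom$x), sum(w * geom$y)) / sum(w)
}

# Temporally align a template to the prototype shapes: find the lag that
# maximizes |correlation| between the template's best channel and any of
# the shapes, and shift the whole template by that lag (zero fill).
align_template <- function(W, shapes) {
  bc <- template_best_channel(W)
  v <- W[bc, ]
  n_t <- length(v)
  best <- c(0, -Inf)
  for (s in seq_len(ncol(shapes))) {
    for (lag in -floor(n_t / 3):floor(n_t / 3)) {
      ia <- max(1, 1 + lag):min(n_t, n_t + lag)
      cc <- abs(sum(v[ia] * shapes[ia - lag, s]))
      if (cc > best[2]) best <- c(lag, cc)
    }
  }
  lag <- best[1]
  if (lag == 0) return(W)
  out <- matrix(0, nrow(W), n_t)
  ia <- max(1, 1 - lag):min(n_t, n_t - lag)
  out[, ia] <- W[, ia + lag]
  out
}

#' Learn spatiotemporal templates from detected spikes
#'
#' Spikes from the simple-template pass are binned into 40-um vertical
#' sections; within each section their embedded PC features are clustered
#' with the graph clusterer and curated by the bimodality criterion alone
#' (no correlogram criterion at this stage). Cluster centroids are mapped
#' back from PC space to channels x time waveforms, all templates are
#' temporally aligned to the prototype shapes, near-duplicates (lagged
#' correlation > `merge_corr` and mean relative difference <
#' `merge_reldiff`) are merged, and each template is stored unit-norm with
#' its average spike norm `x_W`, rank-3 factors, and pairwise lagged cross
#' products.
#'
#' @param spikes Spike tibble with columns `time`, `y`, `amplitude`, and
#'   list-columns `feat` (channels x n_pcs matrices) and `chans` (channel
#'   indices).
#' @param basis n_t x n_pcs orthonormal PC basis.
#' @param geom A [probe_geometry()].
#' @param bin_um Section height (default 40).
#' @param fs Sampling rate (spike times are samples; used for curation
#'   correlograms).
#' @param min_spikes Sections/clusters with fewer spikes are skipped
#'   (default 50: centroids from fewer detections are too noisy to serve
#'   as templates).
#' @param merge_corr,merge_reldiff Duplicate-merge thresholds.
#' @param cluster_args List of overrides for [cluster_features()].
#' @return A `learned_templates` object: `waveforms` (list of unit-norm
#'   channels x n_t), `x_W`, `spatial`/`temporal` rank-3 factors,
#'   `positions`, `lagged_products`.
#' @export
learn_templates <- function(spikes, basis, geom, bin_um = 40, fs = 30000,
                            min_spikes = 50, merge_corr = 0.9,
                            merge_reldiff = 0.25, cluster_args = list()) {
  n_t <- nrow(basis)
  nch <- geom$n_channels
  sec <- floor(spikes$y / bin_um)
  wfs <- list(); xw <- c(); nsp <- c()
  for (s in sort(unique(sec))) {
    idx <- which(sec == s)
    if (length(idx) < min_spikes) next
    U <- sort(unique(unlist(spikes$chans[idx])))
    X <- embed_features(spikes$feat[idx], spikes$chans[idx], U)
    ca <- utils::modifyList(list(n_sub = 25000, k = 10, n_init = 200,
                                 seed = 1), cluster_args)
    cl <- cluster_features(X, n_sub = ca$n_sub, k = ca$k,
                           n_init = ca$n_init, seed = ca$seed)
    tree <- build_merge_tree(cl$graph, cl$labels)
    tv <- traverse_tree(tree, X, cl$labels, use_ccg = FALSE)
    for (g in sort(unique(tv$labels))) {
      mem <- idx[tv$labels == g]
      if (length(mem) < min_spikes) next
      cen <- colMeans(X[tv$labels == g, , drop = FALSE])
      coef <- matrix(cen, nrow = length(U)) # |U| x n_pcs
      Wu <- coef %*% t(basis)               # |U| x n_t
      W <- matrix(0, nch, n_t)
      W[U, ] <- Wu
      nw <- sqrt(sum(W^2))
      if (nw == 0) next
      wfs[[length(wfs) + 1]] <- W / nw
      xw <- c(xw, mean(abs(spikes$amplitude[mem])))
      nsp <- c(nsp, length(mem))
    }
  }
  if (!length(wfs)) stop("no templates learned (too few spikes)")
  shapes <- default_shapes(n_t)
  wfs <- lapply(wfs, align_template, shapes = shapes)
  # merge near-duplicates
  repeat {
    K <- length(wfs)
    merged <- FALSE
    for (i in seq_len(K - 1)) {
      if (merged) break
      for (j in (i + 1):K) {
        cc <- waveform_similarity(wfs[[i]], wfs[[j]])
        # "similar means": relative difference of the norm-scaled
        # waveforms at their best-aligned lag
        rd <- scaled_waveform_reldiff(xw[i] * wfs[[i]], xw[j] * wfs[[j]])
        if (cc > merge_corr && rd < merge_reldiff) {
          w <- nsp[i] / (nsp[i] + nsp[j])
          Wm <- w * wfs[[i]] + (1 - w) * wfs[[j]]
          wfs[[i]] <- Wm / sqrt(sum(Wm^2))
          xw[i] <- w * xw[i] + (1 - w) * xw[j]
          nsp[i] <- nsp[i] + nsp[j]
          wfs[[j]] <- NULL; xw <- xw[-j]; nsp <- nsp[-j]
          merged <- TRUE
          break
        }
      }
    }
    if (!merged) break
  }
  build_learned_templates(wfs, xw, nsp, geom, basis)
}

# Assemble the learned_templates object from raw unit-norm waveforms.
build_learned_templates <- function(wfs, xw, nsp, geom, basis) {
  n_t <- ncol(wfs[[1]])
  spatial <- list(); temporal <- list(); varex <- numeric(length(wfs))
  for (i in seq_along(wfs)) {
    sv <- svd(wfs[[i]], nu = 3, nv = 3)
    spatial[[i]] <- sv$u %*% diag(sv$d[1:3], 3)
    temporal[[i]] <- sv$v
    varex[i] <- sum(sv$d[1:3]^2) / sum(sv$d^2)
  }
  pos <- t(vapply(wfs, template_position, numeric(2), geom = geom))
  lp <- template_lagged_products(wfs, n_t)
  structure(list(waveforms = wfs, x_W = xw, n_spikes = nsp,
                 spatial = spatial, temporal = temporal,
                 rank3_varexp = varex, positions = pos,
                 lagged_products = lp, basis = basis, geom = geom,
                 n_t = n_t),
            class = "learned_templates")
}

#' @export
print.learned_templates <- function(x, ...) {
  cat(sprintf("<learned_templates> %d templates, n_t = %d, mean x_W = %.2f\n",
              length(x$waveforms), x$n_t, mean(x$x_W)))
  invisible(x)
}

# K x K x (2 n_t - 1) array of template cross products at all lags:
# lp[i,j,l] = sum_c sum_t Wi[c, t] Wj[c, t + lag],  lag = l - n_t.
template_lagged_products <- function(wfs, n_t) {
  K <- length(wfs)
  lp <- array(0, c(K, K, 2 * n_t - 1))
  for (i in seq_len(K)) for (j in i:K) {
    for (l in seq_len(2 * n_t - 1)) {
      lag <- l - n_t
      ia <- max(1, 1 - lag):min(n_t, n_t - lag)
      v <- sum(wfs[[i]][, ia + lag] * wfs[[j]][, ia])
      lp[i, j, l] <- v
      lp[j, i, 2 * n_t - l] <- v
    }
  }
  lp
}

# Embed per-spike (channels x n_pcs) features on a union channel set U.
embed_features <- function(feat_list, chan_list, U) {
  n_pcs <- ncol(feat_list[[1]])
  X <- matrix(0, length(feat_list), length(U) * n_pcs)
  for (i in seq_along(feat_list)) {
    rows <- match(chan_list[[i]], U)
    M <- matrix(0, length(U), n_pcs)
    M[rows, ] <- feat_list[[i]]
    X[i, ] <- as.vector(M)
  }
  X
}

#' Matching pursuit with learned templates
#'
#' Iteratively detects and subtracts spikes. Each round computes every
#' template's variance explained `2 x_W W'D - x_W^2` convolutionally via
#' the rank-3 factors, accepts peaks that are local maxima over +/- n_t
#' samples across all templates/channels and above `threshold^2`, and
#' subtracts `x_W W` at every accepted spike before the next round. Rounds
#' stop when no spikes are found or after `n_rounds` (default 50).
#'
#' @param batch A preprocessed `padded_batch`.
#' @param templates A `learned_templates` object.
#' @param threshold Acceptance threshold in norm units (default 8);
#'   acceptance requires `V_explained > threshold^2`.
#' @param n_rounds Maximum detect-subtract rounds.
#' @return List with `spikes` (tibble: `time` absolute sample,
#'   `template_id`, `amplitude` = best-fit scalar `W'D`, `V`) and
#'   `residual` (the `padded_batch` after all subtractions).
#' @export
matching_pursuit <- function(batch, templates, threshold = 8,
                             n_rounds = 50) {
  R <- batch$data
  L <- ncol(R)
  n_t <- templates$n_t
  c0 <- floor(n_t / 2)
  K <- length(templates$waveforms)
  thr2 <- threshold^2
  xw <- templates$x_W
  payload_lo <- batch$n_t + 1
  payload_hi <- batch$n_t + batch$N_T
  out_t <- integer(0); out_k <- integer(0); out_a <- numeric(0)
  out_v <- numeric(0)
  # full rank-3 correlation of every template once; later rounds update it
  # locally through the precomputed lagged template cross products
  corr <- matrix(0, K, L)
  for (k in seq_len(K)) {
    G <- crossprod(templates$spatial[[k]], R) # 3 x L
    corr[k, ] <- cpp_xcorr_sum(G, templates$temporal[[k]], as.integer(c0))
  }
  lp_flat <- as.vector(templates$lagged_products)
  for (round in seq_len(n_rounds)) {
    best <- cpp_mp_best(corr, xw)
    Vbest <- best$V; kbest <- best$k; corr_best <- best$corr
    rm <- cpp_running_max(Vbest, n_t)
    cand <- which(Vbest >= rm & Vbest > thr2)
    cand <- cand[cand >= payload_lo & cand <= payload_hi]
    if (!length(cand)) break
    # enforce min separation n_t (plateau ties), larger V wins
    cand <- cand[order(-Vbest[cand])]
    taken <- integer(0)
    for (t in cand) {
      if (!length(taken) || all(abs(taken - t) > n_t)) taken <- c(taken, t)
    }
    for (t in sort(taken)) {
      k <- kbest[t]
      win <- (t - c0):(t - c0 + n_t - 1)
      R[, win] <- R[, win] - xw[k] * templates$waveforms[[k]]
      cpp_mp_update(corr, lp_flat, K, n_t, k, t, xw[k])
      out_t <- c(out_t, t); out_k <- c(out_k, k)
      out_a <- c(out_a, corr_best[t]); out_v <- c(out_v, Vbest[t])
    }
  }
  ord <- order(out_t)
  batch$data <- R
  list(spikes = tibble::tibble(
         time = batch$t0 + (out_t[ord] - batch$n_t - 1),
         t_local = out_t[ord],
         template_id = out_k[ord], amplitude = out_a[ord], V = out_v[ord]),
       residual = batch)
}

#' PC features with background subtraction
#'
#' For each accepted spike, projects the residual patch on its template's
#' ten nearest channels onto the PC basis, then adds back the (precomputed)
#' PC-space contribution of `x_W` times its own template. Contributions of
#' other overlapping spikes were removed with their templates during
#' matching pursuit, so they do not contaminate the features.
#'
#' @param residual The residual `padded_batch` from [matching_pursuit()].
#' @param spikes The spike tibble from [matching_pursuit()] (needs
#'   `t_local`, `template_id`).
#' @param templates A `learned_templates`.
#' @param basis n_t x n_pcs orthonormal PC basis.
#' @param n_chans Channels per spike (default 10).
#' @return `spikes` with list-columns `feat` (n_chans x n_pcs) and `chans`.
#' @export
features_with_background_subtraction <- function(residual, spikes,
                                                 templates, basis,
                                                 n_chans = 10) {
  geom <- templates$geom
  n_t <- templates$n_t
  c0 <- floor(n_t / 2)
  nch <- geom$n_channels
  n_chans <- min(n_chans, nch)
  # per template: nearest channels and x_W * (W restricted) %*% basis
  tch <- list(); tfeat <- list()
  for (k in seq_along(templates$waveforms)) {
    p <- templates$positions[k, ]
    d2 <- (geom$x - p[1])^2 + (geom$y - p[2])^2
    ch <- order(d2, seq_len(nch))[seq_len(n_chans)]
    tch[[k]] <- ch
    tfeat[[k]] <- templates$x_W[k] *
      (templates$waveforms[[k]][ch, , drop = FALSE] %*% basis)
  }
  L <- ncol(residual$data)
  feat <- vector("list", nrow(spikes)); chans <- vector("list", nrow(spikes))
  flagged <- logical(nrow(spikes))
  for (i in seq_len(nrow(spikes))) {
    k <- spikes$template_id[i]
    t <- spikes$t_local[i]
    win <- (t - c0):(t - c0 + n_t - 1)
    ok <- win >= 1 & win <= L
    patch <- matrix(0, n_chans, n_t)
    patch[, ok] <- residual$data[tch[[k]], win[ok], drop = FALSE]
    flagged[i] <- !all(ok)
    feat[[i]] <- patch %*% basis + tfeat[[k]]
    chans[[i]] <- tch[[k]]
  }
  spikes$feat <- feat
  spikes$chans <- chans
  spikes$flagged <- flagged
  spikes
}


# Relative difference of two scaled waveforms at their best-aligned lag.
scaled_waveform_reldiff <- function(a, b, max_lag = floor(ncol(a) / 2)) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(1)
  n_t <- ncol(a)
  best <- Inf
  for (lag in -max_lag:max_lag) {
    ia <- max(1, 1 + lag):min(n_t, n_t + lag)
    d <- sqrt(sum((a[, ia] - b[, ia - lag])^2))
    if (d < best) best <- d
  }
  best / max(na, nb)
}
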