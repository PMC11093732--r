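# --- prototype waveform shapes and PC basis ---------------------------------

# Parametric biphasic single-channel waveforms: Gaussian trough of varying
# width plus a delayed positive rebound. Used as packaged prototypes when a
# recording yields too few threshold-crossing snippets to learn shapes from.
# `width` is the trough s.d. in samples (real extracellular troughs are
# fast: ~0.07-0.25 ms); `t2p` the trough-to-peak delay in samples, which
# varies semi-independently of trough width.
proto_wave <- function(n_t, width, rebound, t2p = 2.2 * width) {
  c0 <- floor(n_t / 2) # 0-based trough position
  tt <- (0:(n_t - 1)) - c0
  w <- -exp(-tt^2 / (2 * width^2)) +
    rebound * exp(-(tt - t2p)^2 / (2 * pmin(0.5 * t2p, 8)^2))
  w / sqrt(sum(w^2))
}

#' Packaged prototype spike shapes
#' @param n_t Waveform length in samples.
#' @param n_shapes Number of shapes (default 6).
#' @return n_t x n_shapes matrix of unit-norm, trough-centered waveforms.
#' @export
default_shapes <- function(n_t = 61, n_shapes = 6) {
  pars <- data.frame(width = c(1, 1.8, 3, 1.2, 2.2, 3),
                     rebound = c(0.2, 0.25, 0.3, 0.4, 0.35, 0.45),
                     t2p = c(6, 10, 16, 8, 14, 24))
  sapply(seq_len(n_shapes), function(i) {
    p <- pars[(i - 1) %% nrow(pars) + 1, ]
    w <- proto_wave(n_t, p$width, p$rebound, p$t2p)
    # detection operates on high-passed data, so prototype templates are
    # zero-mean (no DC leakage from slow background into the projection)
    w <- w - mean(w)
    w / sqrt(sum(w^2))
  })
}

default_pc_basis <- function(n_t = 61, n_pcs = 6) {
  # PCA of a dense parametric waveform family with jittered alignment
  grid <- expand.grid(width = seq(0.8, 3.5, length.out = 8),
                      rebound = seq(0.1, 0.45, length.out = 6),
                      t2p = c(6, 10, 16, 22),
                      shift = -3:3)
  M <- t(mapply(function(w, r, p, s)
    circshift(proto_wave(n_t, w, r, p), s),
    grid$width, grid$rebound, grid$t2p, grid$shift))
  pr <- stats::prcomp(M, center = FALSE)
  b <- pr$rotation[, seq_len(n_pcs), drop = FALSE]
  qr.Q(qr(b)) # enforce orthonormality
}

#' Learn single-channel spike shapes and a PC basis from a recording
#'
#' Collects threshold-crossing single-channel snippets from preprocessed
#' batches, clusters them with k-means into `n_shapes` unit-norm,
#' trough-aligned centroids, and takes the top `n_pcs` principal components
#' of the snippet matrix. With fewer than 500 snippets the packaged
#' prototype shapes and basis are returned with a warning.
#'
#' @param rec,geom,model,kernel Recording, probe, whitening model, filter.
#' @param n_t Snippet length.
#' @param threshold Detection threshold in units of the channel's robust
#'   s.d. (default 4.5).
#' @param n_shapes,n_pcs Numbers of centroids and PCs.
#' @param N_T Batch size.
#' @param max_batches Snippets are drawn from at most this many batches.
#' @param seed RNG seed for k-means.
#' @return List with `shapes` (n_t x n_shapes) and `basis` (n_t x n_pcs).
#' @export
learn_shapes_and_pcs <- function(rec, geom, model, kernel, n_t = 61,
                                 threshold = 4.5, n_shapes = 6, n_pcs = 6,
                                 N_T = 60000, max_batches = 10, seed = 42) {
  nb <- n_batches(rec, N_T)
  use <- unique(round(seq(0, nb - 1, length.out = min(nb, max_batches))))
  snips <- list()
  c0 <- floor(n_t / 2)
  for (b in use) {
    x <- preprocess_batch(rec, geom, b, model, kernel, N_T = N_T, n_t = n_t)
    d <- x$data
    for (ch in seq_len(nrow(d))) {
      v <- d[ch, ]
      s <- stats::mad(v)
      if (s == 0) next
      ex <- which(-v > threshold * s)
      ex <- ex[ex > n_t & ex < length(v) - n_t]
      if (!length(ex)) next
      keep <- ex[c(TRUE, diff(ex) > n_t)]
      for (t in keep) {
        # re-center on the local trough
        tt <- t - c0 + which.min(v[(t - c0):(t + c0)]) - 1
        if (tt <= c0 || tt + n_t - c0 > length(v)) next
        w <- v[(tt - c0):(tt - c0 + n_t - 1)]
        nw <- sqrt(sum(w^2))
        if (nw > 0) snips[[length(snips) + 1]] <- w / nw
      }
    }
  }
  if (length(snips) < 500) {
    warning("fewer than 500 snippets; falling back to packaged prototypes")
    return(list(shapes = default_shapes(n_t, n_shapes),
                basis = default_pc_basis(n_t, n_pcs)))
  }
  M <- do.call(rbind, snips)
  set.seed(seed)
  km <- stats::kmeans(M, centers = n_shapes, nstart = 5, iter.max = 50)
  shapes <- apply(km$centers, 1, function(w) {
    w <- circshift(w, c0 - (which.min(w) - 1)) # trough to center
    w / sqrt(sum(w^2))
  })
  pr <- stats::prcomp(M, center = FALSE)
  basis <- qr.Q(qr(pr$rotation[, seq_len(n_pcs), drop = FALSE]))
  list(shapes = shapes, basis = basis)
}

# --- simple (universal) template bank ---------------------------------------

#' Build the bank of simple detection templates
#'
#' Simple templates are all combinations of a 2-D spatial position (the
#' channel grid upsampled by 2 in each dimension), one of `n_shapes`
#' single-channel waveform shapes, and one of `n_sizes` isotropic Gaussian
#' spatial envelopes. Waveform shapes and spatial footprints are separately
#' unit-normalized, so each template is unit norm and its variance explained
#' is the squared dot product with the data.
#'
#' @param geom A [probe_geometry()].
#' @param shapes n_t x n_shapes matrix of unit-norm waveforms.
#' @param n_sizes Number of Gaussian sizes (default 5).
#' @param sigmas Optional explicit Gaussian s.d. values in micrometers;
#'   default spans 0.5-3x the vertical pitch.
#' @param n_pos_neighbors Spatial neighborhood used by peak detection
#'   (default 100 nearest positions).
#' @return A `simple_template_bank`.
#' @export
build_simple_templates <- function(geom, shapes = default_shapes(),
                                   n_sizes = 5, sigmas = NULL,
                                   n_pos_neighbors = 100) {
  pos <- template_positions(geom)
  P <- nrow(pos)
  uy <- sort(unique(geom$y))
  dy <- if (length(uy) > 1) stats::median(diff(uy)) else 20
  if (is.null(sigmas))
    sigmas <- dy * seq(0.5, 3, length.out = n_sizes)
  footprints <- lapply(sigmas, function(sg) {
    D2 <- outer(pos[, 1], geom$x, "-")^2 + outer(pos[, 2], geom$y, "-")^2
    F <- exp(-D2 / (2 * sg^2))
    F[F < 0.01] <- 0
    F / sqrt(rowSums(F^2))
  })
  nb <- cpp_knn(pos, pos, min(n_pos_neighbors, P))
  structure(list(positions = pos, shapes = shapes, sizes = sigmas,
                 footprints = footprints, pos_neighbors = nb,
                 n_templates = P * ncol(shapes) * length(sigmas),
                 n_t = nrow(shapes), geom = geom),
            class = "simple_template_bank")
}

#' @export
print.simple_template_bank <- function(x, ...) {
  cat(sprintf("<simple_template_bank> %d positions x %d shapes x %d sizes = %d templates\n",
              nrow(x$positions), ncol(x$shapes), length(x$sizes),
              x$n_templates))
  invisible(x)
}

#' Variance explained by a unit-norm simple template
#'
#' For a unit-norm template the best scalar fit gives
#' `||D||^2 - min_x ||D - x W||^2 = (W' D)^2`.
#'
#' @param W Unit-norm template (any shape).
#' @param D Data patch, same shape.
#' @export
variance_explained_simple <- function(W, D) {
  if (abs(sum(W^2) - 1) > 1e-6) stop("template must be unit norm")
  sum(W * D)^2
}

#' Variance explained by a learned template at its fixed norm
#'
#' Learned templates are matched at their average norm `x_W` rather than a
#' free scalar: `V = 2 x_W W'D - x_W^2`.
#'
#' @param W Unit-norm template.
#' @param x_W Average norm (> 0).
#' @param D Data patch.
#' @export
variance_explained_learned <- function(W, x_W, D) {
  if (abs(sum(W^2) - 1) > 1e-6) stop("template must be unit norm")
  if (x_W <= 0) stop("x_W must be positive")
  2 * x_W * sum(W * D) - x_W^2
}

# Cross-correlation of every channel with kernel k (length n_t, center at
# 0-based position c0): out[ch, t] = sum_tau k[tau] d[ch, t + tau - c0].
# Direct time-domain form: for 61-tap kernels this beats FFT convolution
# and has no circular wrap.
fft_xcorr_channels <- function(d, k, c0) {
  cpp_xcorr_rows(d, k, as.integer(c0))
}

#' Detect spikes with the simple template bank
#'
#' Computes the variance explained of every (position, time) pair --
#' per-shape temporal cross-correlation followed by footprint matrix
#' products, keeping the maximum over shapes and sizes -- and emits peaks
#' that are local maxima over +/- `t_window` samples and the bank's nearest
#' positions, above `threshold` (in template-norm units). Squaring the
#' projection makes each template and its sign-inverted pair share one
#' computation, so positive- and negative-going spikes are both detected.
#'
#' @param batch A preprocessed `padded_batch`.
#' @param bank A `simple_template_bank`.
#' @param threshold Detection threshold in norm units (default 9).
#' @param t_window Temporal half-window for the local-maximum rule
#'   (default 20 samples).
#' @return A tibble: `time` (absolute 0-based sample), `x`, `y` (um),
#'   `amplitude` (signed projection), `pos` (position index), `shape`,
#'   `size`.
#' @export
detect_spikes_universal <- function(batch, bank, threshold = 9,
                                    t_window = 20) {
  d <- batch$data
  L <- ncol(d)
  n_t <- bank$n_t
  c0 <- floor(n_t / 2)
  P <- nrow(bank$positions)
  nS <- ncol(bank$shapes); nZ <- length(bank$sizes)
  corr <- lapply(seq_len(nS), function(s)
    fft_xcorr_channels(d, bank$shapes[, s], c0))
  V <- matrix(-1, P, L)
  best <- matrix(0L, P, L)
  Fall <- do.call(rbind, bank$footprints) # (nZ * P) x n_chan
  for (s in seq_len(nS)) {
    cpp_detect_accumulate(V, best, Fall, corr[[s]], P, nZ, (s - 1L) * nZ)
  }
  Vrm <- cpp_running_max_rows(V, t_window)
  Vnb <- if (ncol(bank$pos_neighbors) == P) cpp_col_max_broadcast(Vrm)
         else cpp_neighbor_max(Vrm, bank$pos_neighbors)
  thr2 <- threshold^2
  hit <- cpp_find_peaks(V, Vnb, thr2, batch$n_t + 1L,
                        batch$n_t + batch$N_T)
  if (!nrow(hit)) {
    return(tibble::tibble(time = numeric(0), x = numeric(0), y = numeric(0),
                          amplitude = numeric(0), pos = integer(0),
                          shape = integer(0), size = integer(0)))
  }
  # greedy suppression of plateau ties: among hits tied within one
  # spatiotemporal neighborhood keep the first by (V, position, time)
  vv <- V[hit]
  ord0 <- order(-vv, hit[, 1], hit[, 2])
  hit <- hit[ord0, , drop = FALSE]
  keep <- rep(TRUE, nrow(hit))
  for (i in seq_len(nrow(hit))) {
    if (!keep[i]) next
    later <- which(keep & seq_len(nrow(hit)) > i)
    if (!length(later)) break
    close_t <- abs(hit[later, 2] - hit[i, 2]) <= t_window
    close_p <- hit[later, 1] %in% bank$pos_neighbors[hit[i, 1], ]
    keep[later[close_t & close_p]] <- FALSE
  }
  hit <- hit[keep, , drop = FALSE]
  p <- hit[, 1]; tt <- hit[, 2]
  id <- best[hit]
  s <- (id - 1L) %/% nZ + 1L
  z <- (id - 1L) %% nZ + 1L
  amp <- numeric(nrow(hit)); sx <- numeric(nrow(hit)); sy <- numeric(nrow(hit))
  for (i in seq_len(nrow(hit))) {
    Fz <- bank$footprints[[z[i]]][p[i], ]
    proj <- corr[[s[i]]][, tt[i]]
    amp[i] <- sum(Fz * proj)
    ch <- which(Fz > 0)
    com <- spike_xy(sign(amp[i]) * proj[ch], bank$geom$x[ch],
                    bank$geom$y[ch])
    sx[i] <- com[1]; sy[i] <- com[2]
  }
  ord <- order(tt)
  tibble::tibble(time = batch$t0 + (tt[ord] - batch$n_t - 1),
                 x = sx[ord], y = sy[ord], amplitude = amp[ord],
                 pos = as.integer(p[ord]), shape = as.integer(s[ord]),
                 size = as.integer(z[ord]))
}

#' Spike position by center of mass of template projections
#'
#' Channel weights are the nonnegative parts of the spike's projection on
#' its best-matching single-channel waveform; the position is the weighted
#' center of mass of the channel coordinates. All-zero weights fall back to
#' the best (largest-projection) channel.
#'
#' @param proj Per-channel projections (sign-corrected so that matching
#'   channels are positive).
#' @param x,y Channel coordinates, micrometers.
#' @return c(x, y) in micrometers.
#' @export
spike_xy <- function(proj, x, y) {
  w <- pmax(proj, 0)
  if (sum(w) == 0) {
    i <- which.max(abs(proj))
    return(c(x[i], y[i]))
  }
  c(sum(w * x), sum(w * y)) / sum(w)
}
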