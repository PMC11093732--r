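# Vertical probe-motion estimation from universal-template detections, and
# the per-batch interpolation operators that undo it.

#' Estimate vertical drift from detected spikes
#'
#' Builds, per time bin (default 2 s), a depth x amplitude histogram of
#' detections (5-um depth bins, ~20 log-spaced amplitude bins), estimates a
#' rigid shift per bin by maximizing the cross-correlation against the
#' element-wise median histogram, then refines per depth block for the
#' nonrigid mode. Bins with fewer than `min_spikes` detections inherit the
#' neighboring estimate and are flagged. This histogram-registration
#' estimator is a deliberate simplification of full iterative registration;
#' the surrounding contracts (2-s bins, inverted-pair detection upstream,
#' linear channel interpolation downstream) are unchanged.
#'
#' @param spikes Tibble with `time` (samples), `y` (um), `amplitude`.
#' @param fs Sampling rate, Hz.
#' @param bin_s Time-bin size, seconds (default 2).
#' @param n_blocks Number of depth blocks (default 6; 1 = rigid).
#' @param depth_bin_um Depth histogram resolution (default 5).
#' @param n_amp_bins Amplitude bins, log-spaced (default 20).
#' @param max_shift_um Largest shift searched (default 40).
#' @param min_spikes Minimum detections per usable bin (default 10).
#' @param y_range Optional c(min, max) probe depth range, um.
#' @return A `drift_trace`: `values` (time bins x blocks, um),
#'   `block_centers`, `bin_s`, `flagged`.
#' @export
estimate_drift <- function(spikes, fs, bin_s = 2, n_blocks = 1,
                           depth_bin_um = 5, n_amp_bins = 20,
                           max_shift_um = 40, min_spikes = 10,
                           y_range = NULL) {
  tsec <- spikes$time / fs
  if (length(tsec) && diff(range(tsec)) < bin_s)
    stop("spikes must span at least 2 time bins")
  nb <- max(2, ceiling(max(tsec) / bin_s))
  if (is.null(y_range)) y_range <- range(spikes$y)
  ybr <- seq(y_range[1] - depth_bin_um, y_range[2] + depth_bin_um,
             by = depth_bin_um)
  ny <- length(ybr) - 1
  amp <- abs(spikes$amplitude)
  abr <- exp(seq(log(max(min(amp), 1e-6)), log(max(amp) + 1e-6),
                 length.out = n_amp_bins + 1))
  tb <- pmin(nb, floor(tsec / bin_s) + 1)
  yb <- pmin(ny, pmax(1, findInterval(spikes$y, ybr)))
  ab <- pmin(n_amp_bins, pmax(1, findInterval(amp, abr)))
  H <- array(0, c(nb, ny, n_amp_bins))
  for (i in seq_along(tb)) H[tb[i], yb[i], ab[i]] <- H[tb[i], yb[i], ab[i]] + 1
  counts <- tabulate(tb, nbins = nb)
  ref <- apply(H, c(2, 3), stats::median)
  # sparse histograms have an all-zero element-wise median; the mean
  # reference carries the same registration information and stays defined
  if (all(ref == 0)) ref <- apply(H, c(2, 3), mean)
  max_lag <- max(1, round(max_shift_um / depth_bin_um))
  shift_of <- function(h, refh) {
    cc <- vapply(-max_lag:max_lag, function(l) {
      ia <- max(1, 1 + l):min(ny, ny + l)
      sum(h[ia, , drop = FALSE] * refh[ia - l, , drop = FALSE])
    }, numeric(1))
    best <- which.max(cc)
    if (cc[best] <= 0) return(0) # no histogram overlap: no evidence
    # parabolic sub-bin refinement
    if (best > 1 && best < length(cc)) {
      num <- cc[best - 1] - cc[best + 1]
      den <- cc[best - 1] - 2 * cc[best] + cc[best + 1]
      frac <- if (den != 0) 0.5 * num / den else 0
      ((-max_lag:max_lag)[best] + max(-0.5, min(0.5, frac))) * depth_bin_um
    } else {
      (-max_lag:max_lag)[best] * depth_bin_um
    }
  }
  rigid <- vapply(seq_len(nb), function(b)
    shift_of(H[b, , , drop = TRUE], ref), numeric(1))
  # iterative refinement: rebuild the reference from back-shifted
  # histograms so large drift does not smear it, then re-register
  shift_rows <- function(h, r) {
    if (r == 0) return(h)
    out <- h * 0
    src <- seq_len(ny) + r
    ok <- src >= 1 & src <= ny
    out[which(ok), ] <- h[src[ok], , drop = FALSE]
    out
  }
  for (iter in 1:3) {
    acc <- 0
    for (b in seq_len(nb))
      acc <- acc + shift_rows(H[b, , , drop = TRUE],
                              round(rigid[b] / depth_bin_um))
    ref <- acc / nb
    rigid <- vapply(seq_len(nb), function(b)
      shift_of(H[b, , , drop = TRUE], ref), numeric(1))
  }
  flagged <- counts < min_spikes
  # flagged bins inherit the nearest valid neighbor
  if (any(flagged) && !all(flagged)) {
    ok <- which(!flagged)
    for (b in which(flagged)) rigid[b] <- rigid[ok[which.min(abs(ok - b))]]
  }
  # gauge fixing: drift is defined relative to the reference whose phase
  # is arbitrary; report shifts around the recording mean position
  rigid <- rigid - mean(rigid[!flagged])
  blocks <- seq(y_range[1], y_range[2], length.out = n_blocks + 2)
  centers <- blocks[2:(n_blocks + 1)]
  vals <- matrix(rigid, nb, n_blocks)
  if (n_blocks > 1) {
    span <- diff(y_range)
    half <- span / n_blocks
    for (k in seq_len(n_blocks)) {
      sel <- ybr[-length(ybr)] + depth_bin_um / 2 >= centers[k] - half &
        ybr[-length(ybr)] + depth_bin_um / 2 <= centers[k] + half
      if (sum(sel) < 3) next
      refk <- ref[sel, , drop = FALSE]
      nyk <- sum(sel)
      for (b in seq_len(nb)) {
        if (flagged[b]) next
        hk <- H[b, sel, , drop = TRUE]
        if (is.null(dim(hk))) hk <- matrix(hk, nyk)
        cc <- vapply(-max_lag:max_lag, function(l) {
          ia <- max(1, 1 + l):min(nyk, nyk + l)
          if (!length(ia)) return(0)
          sum(hk[ia, , drop = FALSE] * refk[ia - l, , drop = FALSE])
        }, numeric(1))
        if (max(cc) > 0)
          vals[b, k] <- (rigid[b] +
            ((-max_lag:max_lag)[which.max(cc)]) * depth_bin_um) / 2
      }
    }
    # light temporal smoothing of block refinements around the rigid trace
    for (k in seq_len(n_blocks))
      vals[, k] <- rigid + gauss_smooth(vals[, k] - rigid, 2)
  }
  structure(list(values = vals, block_centers = centers, bin_s = bin_s,
                 flagged = flagged, rigid = rigid, y_range = y_range),
            class = "drift_trace")
}

#' @export
print.drift_trace <- function(x, ...) {
  cat(sprintf("<drift_trace> %d bins x %d blocks, range [%.1f, %.1f] um\n",
              nrow(x$values), ncol(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Tidy a drift trace
#' @param x A `drift_trace`.
#' @param ... Unused.
#' @export
tidy.drift_trace <- function(x, ...) {
  nb <- nrow(x$values); nk <- ncol(x$values)
  tibble::tibble(time_bin = rep(seq_len(nb), nk),
                 time_s = rep((seq_len(nb) - 0.5) * x$bin_s, nk),
                 block = rep(seq_len(nk), each = nb),
                 shift_um = as.vector(x$values))
}

#' Interpolate a drift trace to every channel
#'
#' Linear interpolation across block centers with constant extrapolation
#' beyond the outer blocks; a single (rigid) block gives every channel the
#' same shift.
#'
#' @param trace A `drift_trace`.
#' @param geom A [probe_geometry()].
#' @return time bins x channels matrix of shifts (um).
#' @export
drift_to_channels <- function(trace, geom) {
  nb <- nrow(trace$values)
  nk <- ncol(trace$values)
  if (nk == 1)
    return(matrix(trace$values[, 1], nb, geom$n_channels))
  t(vapply(seq_len(nb), function(b)
    stats::approx(trace$block_centers, trace$values[b, ], xout = geom$y,
                  rule = 2)$y, numeric(geom$n_channels)))
}

#' Kriging interpolation operator for one batch
#'
#' Builds the channel-space operator
#' `K(x_nominal, x_shifted) (K(x_shifted, x_shifted) + lambda I)^-1`
#' with a Gaussian kernel: it maps data sampled at the shifted channel
#' positions back onto the nominal positions.
#'
#' @param channel_shifts Per-channel vertical shifts, um (positive = the
#'   shifted sampling position is above the nominal one).
#' @param geom A [probe_geometry()].
#' @param sigma Gaussian s.d., um (default 20).
#' @param lambda Regularization (default 0.01).
#' @return n_chan x n_chan operator matrix.
#' @export
build_shift_matrix <- function(channel_shifts, geom, sigma = 20,
                               lambda = 0.01) {
  nominal <- cbind(geom$x, geom$y)
  shifted <- cbind(geom$x, geom$y + channel_shifts)
  kriging_weights(nominal, shifted, sigma = sigma, lambda = lambda)
}

#' Estimate drift for a whole recording and build per-batch operators
#'
#' Runs universal-template detection on every batch (preprocessed without
#' alignment), estimates the drift trace in 2-s bins, interpolates it to
#' channels, and returns one interpolation operator per batch. Because the
#' estimated drift is the apparent motion of the units, the correction
#' samples each channel at its position plus the drift, i.e. the shift
#' matrix is built from the negated per-channel trace.
#'
#' @param rec,geom,model,kernel Recording, probe, whitening model, filter.
#' @param bank A `simple_template_bank`.
#' @param config A [spikegraph_config()].
#' @return List with `trace` (`drift_trace`), `shift_matrices` (list, one
#'   per batch), `spikes` (the universal detections used).
#' @export
correct_drift <- function(rec, geom, model, kernel, bank, config) {
  cfg <- config
  nb <- n_batches(rec, cfg$N_T)
  sp <- vector("list", nb)
  for (b in seq_len(nb) - 1L) {
    x <- preprocess_batch(rec, geom, b, model, kernel,
                          N_T = cfg$N_T, n_t = cfg$n_t)
    sp[[b + 1]] <- detect_spikes_universal(x, bank,
                                           threshold = cfg$threshold_universal)
  }
  spikes <- dplyr::bind_rows(sp)
  n_blocks <- if (cfg$rigid_only) 1 else cfg$n_blocks
  trace <- estimate_drift(spikes, fs = rec$sampling_rate,
                          bin_s = cfg$drift_bin_s, n_blocks = n_blocks,
                          y_range = range(geom$y))
  chsh <- drift_to_channels(trace, geom)
  batch_s <- cfg$N_T / rec$sampling_rate
  mats <- lapply(seq_len(nb) - 1L, function(b) {
    tmid <- (b + 0.5) * batch_s
    bin <- min(nrow(chsh), max(1, floor(tmid / trace$bin_s) + 1))
    build_shift_matrix(-chsh[bin, ], geom, sigma = cfg$kriging_sigma,
                       lambda = cfg$kriging_lambda)
  })
  list(trace = trace, shift_matrices = mats, spikes = spikes)
}
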