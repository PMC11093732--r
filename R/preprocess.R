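#' Common average referencing
#'
#' Removes each channel's temporal mean over the batch, then the
#' cross-channel median at every sample. The median step cancels artifacts
#' shared across channels (room noise, optogenetic transients) and must run
#' before filtering and whitening so large artifacts do not leak into
#' neighboring samples.
#'
#' @param batch A `padded_batch` (or bare channels x time matrix).
#' @return Same type as the input.
#' @export
common_average_reference <- function(batch) {
  d <- if (inherits(batch, "padded_batch")) batch$data else batch
  d <- d - rowMeans(d)
  if (nrow(d) >= 2) {
    d <- sweep(d, 2, cpp_col_median(d))
  } else {
    warning("single-channel input: skipping cross-channel median")
  }
  if (inherits(batch, "padded_batch")) { batch$data <- d; batch } else d
}

#' High-pass FIR kernel matched to a Butterworth response
#'
#' The kernel is the response of a causal order-`order` Butterworth
#' high-pass (single forward pass) to a unit impulse placed at index
#' `floor(N_T / 2)` (0-based) of a zero vector of length `N_T`, so applying
#' it by FFT convolution reproduces the recursive filter.
#'
#' @param cutoff Cutoff frequency, Hz (default 300).
#' @param N_T Kernel length in samples.
#' @param fs Sampling rate, Hz.
#' @param order Butterworth order (default 3).
#' @return A `filter_kernel`: list with `h` (length `N_T`), `center`
#'   (0-based impulse position), `cutoff`, `fs`.
#' @export
build_highpass_kernel <- function(cutoff = 300, N_T = 60000, fs = 30000,
                                  order = 3) {
  if (cutoff <= 0 || cutoff >= fs / 2)
    stop("cutoff must lie in (0, fs/2)")
  bw <- signal::butter(order, cutoff / (fs / 2), type = "high")
  x <- numeric(N_T)
  ctr <- floor(N_T / 2)
  x[ctr + 1] <- 1
  h <- as.numeric(signal::filter(bw, x))
  structure(list(h = h, center = ctr, cutoff = cutoff, fs = fs,
                 order = order), class = "filter_kernel")
}

#' Apply an FIR kernel in FFT space
#'
#' Performs circular convolution of every channel with the kernel over the
#' full padded batch; the circular wrap-around is confined to the padding
#' region, so the payload equals the linear (recursive-filter) result.
#'
#' @param batch A `padded_batch` (or channels x time matrix).
#' @param kernel A `filter_kernel` from [build_highpass_kernel()].
#' @return Same type as input, filtered.
#' @export
apply_filter_fft <- function(batch, kernel) {
  d <- if (inherits(batch, "padded_batch")) batch$data else batch
  L <- ncol(d)
  if (length(kernel$h) > L) stop("kernel longer than padded batch")
  # causal tail of the impulse response (zero before the impulse); its
  # exponential decay lets us truncate far below machine precision and run
  # the FFT at a fast power-of-two length with no circular wrap
  ht <- kernel$h[(kernel$center + 1):length(kernel$h)]
  q <- max(which(abs(ht) > 1e-13 * max(abs(ht))))
  ht <- ht[seq_len(q)]
  Lp <- stats::nextn(L + q)
  H <- stats::fft(c(ht, numeric(Lp - q)))
  Y <- stats::mvfft(rbind(t(d), matrix(0, Lp - L, nrow(d))))
  out <- t(Re(stats::mvfft(Y * H, inverse = TRUE))[seq_len(L), ,
                                                   drop = FALSE] / Lp)
  if (inherits(batch, "padded_batch")) { batch$data <- out; batch } else out
}

#' Fit a local ZCA whitening model
#'
#' The channel covariance is estimated from CAR-ed, high-pass filtered
#' batches subsampled evenly across the recording (biased, 1/T normalized).
#' For each channel, the covariance of its `n_neighbors` nearest channels
#' (Euclidean distance in probe micrometers, ties broken by channel index)
#' is inverted with epsilon-smoothed singular values,
#' `W = U (S + eps I)^{-1/2} U^T`, and only that channel's whitening vector
#' is kept, embedded at its neighbors' columns of the full matrix. Keeping
#' 32 coefficients per channel instead of `n_chan` prevents overfitting on
#' large probes.
#'
#' @param rec A [recording_handle()] (or a precomputed covariance matrix,
#'   accepted for testing via `cov_matrix`).
#' @param geom A [probe_geometry()].
#' @param n_neighbors Neighborhood size in channels (default 32).
#' @param epsilon Smoothing constant; default `1e-6 * mean(S)` per
#'   neighborhood.
#' @param kernel Optional precomputed filter kernel.
#' @param N_T,n_t Batch geometry.
#' @param max_batches Covariance is estimated from at most this many evenly
#'   spaced batches (default 25).
#' @param cov_matrix Optional covariance to use directly.
#' @return A `whitening_model`: list with `W_white` (n_chan x n_chan), `C`,
#'   and per-neighborhood factors retained for diagnostics.
#' @export
fit_whitening <- function(rec = NULL, geom, n_neighbors = 32, epsilon = NULL,
                          kernel = NULL, N_T = 60000, n_t = 61,
                          max_batches = 25, cov_matrix = NULL) {
  nch <- geom$n_channels
  if (is.null(cov_matrix)) {
    nb <- n_batches(rec, N_T)
    use <- unique(round(seq(0, nb - 1, length.out = min(nb, max_batches))))
    if (is.null(kernel))
      kernel <- build_highpass_kernel(N_T = N_T, fs = rec$sampling_rate)
    C <- matrix(0, nch, nch); tot <- 0
    for (b in use) {
      x <- load_batch(rec, geom, b, N_T, n_t)
      x <- apply_filter_fft(common_average_reference(x), kernel)
      p <- batch_payload(x)
      C <- C + tcrossprod(p)
      tot <- tot + ncol(p)
    }
    C <- C / tot
  } else C <- cov_matrix
  if (any(!is.finite(C))) stop("non-finite covariance")
  k <- min(n_neighbors, nch)
  W <- matrix(0, nch, nch)
  for (i in seq_len(nch)) {
    d2 <- (geom$x - geom$x[i])^2 + (geom$y - geom$y[i])^2
    idx <- order(d2, seq_len(nch))[seq_len(k)]
    Cs <- C[idx, idx, drop = FALSE]
    e <- eigen(Cs, symmetric = TRUE)
    S <- pmax(e$values, 0)
    eps <- if (is.null(epsilon)) 1e-6 * mean(S) else epsilon
    Wi <- e$vectors %*% ((1 / sqrt(S + eps)) * t(e$vectors))
    W[i, idx] <- Wi[match(i, idx), ]
  }
  structure(list(W_white = W, C = C, n_neighbors = k),
            class = "whitening_model")
}

#' Apply whitening and drift alignment in one matrix product
#'
#' The whitening matrix and the per-batch drift interpolation operator are
#' both channel-space linear maps, so they are combined into a single
#' `n_chan x n_chan` product before being applied to the batch.
#'
#' @param batch A `padded_batch` (or matrix).
#' @param model A `whitening_model` (or bare matrix).
#' @param shift_matrix Per-batch interpolation operator; identity when drift
#'   correction is off.
#' @return Same type as input.
#' @export
apply_whitening_and_alignment <- function(batch, model,
                                          shift_matrix = NULL) {
  W <- if (inherits(model, "whitening_model")) model$W_white else model
  d <- if (inherits(batch, "padded_batch")) batch$data else batch
  if (nrow(d) != ncol(W)) stop("dimension mismatch between batch and model")
  M <- if (is.null(shift_matrix)) W else {
    if (!all(dim(shift_matrix) == dim(W)))
      stop("dimension mismatch between shift matrix and whitening model")
    W %*% shift_matrix
  }
  out <- M %*% d
  if (inherits(batch, "padded_batch")) { batch$data <- out; batch } else out
}

# Full preprocessing of one batch: CAR -> filter -> whiten (+ alignment).
preprocess_batch <- function(rec, geom, b, model, kernel, shift_matrix = NULL,
                             N_T = 60000, n_t = 61) {
  x <- load_batch(rec, geom, b, N_T, n_t)
  x <- common_average_reference(x)
  x <- apply_filter_fft(x, kernel)
  apply_whitening_and_alignment(x, model, shift_matrix)
}
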