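# Synthetic drifting-recording simulator with ground truth.
#
# The waveform bank, inter-spike-interval library and channel-correlation
# matrix are parametric synthetic stand-ins with matched statistics
# (biphasic waveforms with 0.2-1 ms trough-to-peak, Gaussian spatial
# footprints of 20-40 um, gamma ISIs with a refractory floor, an
# AR(1)-in-space correlation matrix). All bank-processing code paths (PC
# denoising, depth-variation filtering, kriging upsampling) run on these
# stand-ins unchanged and accept a user-supplied bank.

#' Gaussian kriging interpolation weights
#'
#' Weights mapping values sampled at `src` positions to `dst` positions:
#' `K(dst, src) (K(src, src) + lambda I)^-1` with an isotropic Gaussian
#' kernel. Positions may be 1-D (depths) or 2-D (n x 2 matrices).
#'
#' @param dst,src Positions (vector or n x 2 matrix), micrometers.
#' @param sigma Gaussian s.d., micrometers (default 20).
#' @param lambda Regularization (default 0.01). If the system is singular
#'   the regularization is increased tenfold with a warning.
#' @return length(dst) x length(src) weight matrix.
#' @export
kriging_weights <- function(dst, src, sigma = 20, lambda = 0.01) {
  stopifnot(sigma > 0)
  if (is.null(dim(dst))) dst <- cbind(0, dst)
  if (is.null(dim(src))) src <- cbind(0, src)
  d2 <- function(a, b) outer(a[, 1], b[, 1], "-")^2 +
    outer(a[, 2], b[, 2], "-")^2
  Kds <- exp(-d2(dst, src) / (2 * sigma^2))
  Kss <- exp(-d2(src, src) / (2 * sigma^2))
  repeat {
    M <- try(solve(Kss + diag(lambda, nrow(Kss))), silent = TRUE)
    if (!inherits(M, "try-error")) break
    lambda <- lambda * 10
    warning("kriging system singular; increasing lambda to ", lambda)
  }
  Kds %*% M
}

#' Generate a synthetic waveform bank across depths
#'
#' Each unit is a biphasic temporal shape times a Gaussian spatial
#' footprint, sampled at 20 depth bins of 2 um (total 40 um), with small
#' depth-dependent shape perturbations emulating real waveform changes
#' under drift. The bank is then processed the way a recording-derived
#' bank is: each unit is denoised by reconstruction from its top three
#' depth PCs, normalized by its average norm across depths, filtered by
#' depth variation (Euclidean distance between the -20 um waveform and the
#' +20 um waveform shifted up by the equivalent of 40 um must not exceed
#' 0.25), and upsampled x100 in depth by kriging (sd 20 um, lambda 0.01).
#'
#' @param n_units Number of units to draw (before filtering).
#' @param geom A [probe_geometry()].
#' @param seed RNG seed.
#' @param n_t Waveform length in samples (default 61).
#' @param morph S.d. of the depth-dependent shape perturbation (default
#'   0.04; raise it to exercise the variation filter).
#' @param fs Sampling rate (trough-to-peak times are drawn in 0.2-1 ms).
#' @param aligned_sites If TRUE, waveforms are interpolated onto vertically
#'   aligned sites (the step-drift-aligned variant).
#' @return A `waveform_bank`: list with per-unit `waveforms` (list of 20
#'   channels x n_t matrices), `depths` (the 20 bin offsets, um),
#'   `kriging` (weights for the x100 upsampled depth grid), `variation`,
#'   `upsampled_depths`, `geom`.
#' @export
generate_waveform_bank <- function(n_units, geom, seed = 1, n_t = 61,
                                   morph = 0.04, fs = 30000,
                                   aligned_sites = FALSE) {
  set.seed(seed)
  depth_bins <- seq(-19, 19, by = 2) # 20 bins of 2 um
  gx <- if (aligned_sites) rep(stats::median(geom$x), geom$n_channels) else geom$x
  gy <- geom$y
  uy <- sort(unique(gy))
  pitch <- if (length(uy) > 1) stats::median(diff(uy)) else 20
  units <- list()
  for (u in seq_len(n_units)) {
    t2p_ms <- runif(1, 0.2, 1)
    t2p <- t2p_ms * fs / 1000
    width <- runif(1, 1, 3.5) # trough s.d., samples (~0.08-0.3 ms FWHM)
    rebound <- runif(1, 0.15, 0.45)
    # real extracellular waveforms are diverse: asymmetric troughs and an
    # occasional positive pre-deflection decorrelate units that would
    # otherwise share one narrow parametric form
    skew <- runif(1, 0.6, 1.6)      # right/left trough width ratio
    prepk <- runif(1, 0, 0.3)       # pre-peak amplitude (fraction)
    pre_t <- -runif(1, 3, 8)        # pre-peak position, samples
    fsig <- runif(1, 20, 40)
    ux <- runif(1, min(gx), max(gx))
    uy0 <- runif(1, min(gy) + 2 * pitch, max(gy) - 2 * pitch)
    wfs <- lapply(depth_bins, function(d) {
      shape <- unit_wave(n_t, width * (1 + morph * d / 20 * rnorm(1)),
                         rebound * (1 + morph * d / 20 * rnorm(1)), t2p,
                         skew, prepk, pre_t)
      amp <- exp(-((gx - ux)^2 + (gy - (uy0 + d))^2) / (2 * fsig^2))
      outer(amp, shape)
    })
    units[[u]] <- list(wfs = wfs, x = ux, y = uy0, fsig = fsig)
  }
  # top-3 PC denoising across depths
  for (u in seq_along(units)) {
    M <- t(vapply(units[[u]]$wfs, as.vector,
                  numeric(geom$n_channels * n_t)))
    mu <- colMeans(M)
    sv <- svd(sweep(M, 2, mu), nu = 3, nv = 3)
    Md <- sweep(sv$u %*% diag(sv$d[1:3], 3) %*% t(sv$v), 2, mu, "+")
    units[[u]]$wfs <- lapply(seq_len(20), function(i)
      matrix(Md[i, ], geom$n_channels, n_t))
  }
  # average-norm normalization
  for (u in seq_along(units)) {
    nrm <- mean(vapply(units[[u]]$wfs, function(w) sqrt(sum(w^2)),
                       numeric(1)))
    units[[u]]$wfs <- lapply(units[[u]]$wfs, function(w) w / nrm)
  }
  # depth-variation filter: compare -20 um waveform with +20 um waveform
  # shifted up by 40 um worth of channels
  ch_per_row <- max(1, geom$n_channels %/% length(uy))
  n_shift <- min(geom$n_channels - 1, round(40 / pitch) * ch_per_row)
  variation <- vapply(units, function(un) {
    a <- un$wfs[[1]]; b <- un$wfs[[20]]
    ia <- 1:(geom$n_channels - n_shift)
    sqrt(sum((a[ia, ] - b[ia + n_shift, ])^2))
  }, numeric(1))
  keep <- variation <= 0.25
  if (!any(keep))
    stop("all units filtered by depth variation; lower `morph`")
  units <- units[keep]
  up <- seq(depth_bins[1], depth_bins[20], by = 2 / 100)
  kw <- kriging_weights(up, depth_bins, sigma = 20, lambda = 0.01)
  # renormalize by average norm across upsampled depths (norms are
  # essentially preserved by interpolation; applied per unit at sampling)
  structure(list(units = units, depths = depth_bins,
                 upsampled_depths = up, kriging = kw,
                 variation = variation[keep], geom = geom, n_t = n_t),
            class = "waveform_bank")
}

#' Waveform of one bank unit at an arbitrary depth offset
#'
#' Kriging interpolation of the unit's 20 depth-binned waveforms at the
#' requested offset (clamped to the bank's +/- 19 um range).
#'
#' @param bank A `waveform_bank`.
#' @param unit Unit index.
#' @param depth Depth offset, micrometers.
#' @export
bank_waveform <- function(bank, unit, depth) {
  depth <- min(max(depth, bank$depths[1]), bank$depths[length(bank$depths)])
  w <- kriging_weights(depth, bank$depths, sigma = 20, lambda = 0.01)
  wfs <- bank$units[[unit]]$wfs
  out <- 0
  for (i in seq_along(wfs)) out <- out + w[1, i] * wfs[[i]]
  out
}

#' Generate a drift profile
#'
#' Implements the five stated drift conditions for a recording of
#' `duration_s` seconds at `n_pos` probe positions in 2-s bins (200 ms for
#' the fast condition):
#' * `none`: identically zero.
#' * `medium`: overall trace = Gaussian noise smoothed in time (sigma =
#'   100 s); per-position traces additionally smoothed across positions
#'   (sigma = 2 positions), scaled by 0.4 and added; the whole matrix is
#'   affinely rescaled so its minimum/maximum are exactly -7/+7 um.
#' * `high`: per-position scale 0.26, rescale to -18.5/+18.5 um.
#' * `step`: per-position scale 0.58, rescale to -4/+4 um, then 30 um added
#'   to every position from the midpoint on.
#' * `fast`: a medium profile upsampled to 200-ms bins (nearest neighbor)
#'   plus 300 fast events of 10 um amplitude with a
#'   difference-of-exponentials kernel (rise 80 ms, decay 200 ms) at
#'   random times.
#'
#' @param kind One of `"none"`, `"medium"`, `"high"`, `"fast"`, `"step"`,
#'   `"step_aligned"`.
#' @param duration_s Recording length, seconds (default 2700 = 45 min).
#' @param n_pos Number of probe positions (default 9).
#' @param seed RNG seed.
#' @return A `drift_profile`: `trace` (time bins x positions, um),
#'   `bin_s`, `kind`, `positions` (relative 0..1 along the probe).
#' @export
generate_drift <- function(kind = c("none", "medium", "high", "fast",
                                    "step", "step_aligned"),
                           duration_s = 2700, n_pos = 9, seed = 1) {
  kind <- match.arg(kind)
  set.seed(seed)
  bin_s <- if (kind == "fast") 0.2 else 2
  nb <- ceiling(duration_s / 2) # slow component always lives in 2-s bins
  base <- function(scale, mm) {
    sig_t <- 100 / 2
    overall <- gauss_smooth(rnorm(nb), sig_t)
    per <- matrix(rnorm(nb * n_pos), nb, n_pos)
    per <- apply(per, 2, gauss_smooth, sigma = sig_t)
    per <- t(apply(per, 1, gauss_smooth, sigma = 2))
    d <- overall + scale * per
    (d - min(d)) / (max(d) - min(d)) * 2 * mm - mm
  }
  trace <- switch(kind,
    none = matrix(0, nb, n_pos),
    medium = base(0.4, 7),
    high = base(0.26, 18.5),
    step = ,
    step_aligned = {
      d <- base(0.58, 4)
      d[seq_len(nb) > nb / 2, ] <- d[seq_len(nb) > nb / 2, ] + 30
      d
    },
    fast = {
      slow <- base(0.4, 7)
      nf <- ceiling(duration_s / 0.2)
      up <- slow[pmin(nb, ceiling(seq_len(nf) * 0.2 / 2)), , drop = FALSE]
      tt <- seq_len(nf) * 0.2
      kern <- function(t0) {
        dt <- tt - t0
        k <- ifelse(dt < 0, 0, exp(-dt / 0.2) - exp(-dt / 0.08))
        k / max(k) * 10
      }
      ev <- runif(300, 0, duration_s)
      f <- rowSums(vapply(ev, kern, numeric(nf)))
      up + f
    })
  structure(list(trace = trace, bin_s = bin_s, kind = kind,
                 positions = seq(0, 1, length.out = n_pos)),
            class = "drift_profile")
}

# drift (um) for every channel at a vector of times (seconds)
drift_at <- function(profile, times, channel_rel) {
  nb <- nrow(profile$trace)
  bins <- pmin(nb, pmax(1, floor(times / profile$bin_s) + 1))
  vapply(seq_along(times), function(i) {
    stats::approx(profile$positions, profile$trace[bins[i], ],
                  xout = channel_rel, rule = 2)$y
  }, numeric(length(channel_rel)))
}

#' Synthetic reference ISI library
#'
#' Gamma-distributed inter-spike-interval sets with an absolute refractory
#' floor, standing in for a library of recorded units; mean rates are
#' log-normal around ~12.6 Hz.
#'
#' @param n_sets Number of reference units.
#' @param duration_s Span covered by each set.
#' @param seed RNG seed.
#' @export
reference_isi_library <- function(n_sets = 50, duration_s = 2700,
                                  seed = 1) {
  set.seed(seed)
  rates <- pmin(40, stats::rlnorm(n_sets, log(9), 0.6) + 1)
  lapply(rates, function(r) {
    n <- max(2, round(r * duration_s))
    shape <- runif(1, 1, 3)
    isi <- stats::rgamma(n, shape = shape, rate = shape * r) + 0.003
    isi
  })
}

#' Simulate ground-truth spike trains and norms
#'
#' Single-unit trains shuffle the ISIs of a randomly chosen reference set
#' (preserving the ISI multiset, hence the refractory floor); multi-unit
#' trains are Poisson with rates drawn from the reference rate
#' distribution. Norms: single = 10 + Exponential(mean 7); multi =
#' Uniform(4, 10).
#'
#' @param bank A `waveform_bank`.
#' @param duration_s Recording length, seconds.
#' @param n_single,n_multi Unit counts; defaults use all bank units as
#'   single-units.
#' @param isi_library Optional list of ISI vectors.
#' @param min_norm Optional lower truncation for single-unit norms.
#' @param seed RNG seed.
#' @return A `ground_truth`: tibble `units` (unit, class, norm, bank_unit)
#'   and list `trains` of spike times in seconds.
#' @export
generate_spike_trains <- function(bank, duration_s, n_single = NULL,
                                  n_multi = 0, isi_library = NULL,
                                  min_norm = NULL, seed = 1) {
  set.seed(seed)
  if (is.null(n_single)) n_single <- length(bank$units)
  if (is.null(isi_library))
    isi_library <- reference_isi_library(50, duration_s, seed = seed + 1)
  rates <- vapply(isi_library, function(x) 1 / mean(x), numeric(1))
  trains <- list(); cls <- character(0); norms <- numeric(0)
  bu <- integer(0)
  n_bank <- length(bank$units)
  for (i in seq_len(n_single + n_multi)) {
    single <- i <= n_single
    if (single) {
      isi <- sample(isi_library[[sample.int(length(isi_library), 1)]])
      st <- cumsum(isi)
      st <- st[st < duration_s]
      nrm <- 10 + rexp(1, 1 / 7)
      if (!is.null(min_norm)) while (nrm < min_norm) nrm <- 10 + rexp(1, 1 / 7)
    } else {
      r <- sample(rates, 1)
      st <- sort(runif(stats::rpois(1, r * duration_s), 0, duration_s))
      nrm <- runif(1, 4, 10)
    }
    if (length(st) < 2) {
      warning("unit ", i, " has fewer than 2 spikes; skipped")
      next
    }
    trains[[length(trains) + 1]] <- st
    cls <- c(cls, if (single) "single" else "multi")
    norms <- c(norms, nrm)
    bu <- c(bu, (i - 1) %% n_bank + 1)
  }
  structure(list(units = tibble::tibble(unit = seq_along(trains),
                                        class = cls, norm = norms,
                                        bank_unit = bu),
                 trains = trains, duration_s = duration_s),
            class = "ground_truth")
}

#' Render a simulated recording to disk
#'
#' Adds every unit's depth-appropriate waveform (depth = nominal + drift at
#' the spike time) at its spike times -- spike trains are added in three
#' interleaved parts so that colliding spikes superpose exactly -- then
#' white per-channel noise at s.d. `noise_sd` (flat spectrum up to 300 Hz
#' and beyond; a band-limited variant is available via `noise_lowpass`),
#' multiplies by the inverse of a synthetic whitening matrix
#' (AR(1) channel correlations), scales by 200, clips at +/-32767 and
#' writes int16, plus a JSON ground-truth sidecar and probe file.
#'
#' @param bank A `waveform_bank`.
#' @param truth A `ground_truth`.
#' @param profile A `drift_profile`.
#' @param geom A [probe_geometry()].
#' @param path Output binary path (sidecars get `.truth.json`,
#'   `.probe.json` suffixes).
#' @param fs Sampling rate (default 30,000 Hz).
#' @param noise_sd Pre-unwhitening noise s.d. (default 0.76; 0 disables).
#' @param noise_lowpass Optional low-pass cutoff (Hz) applied to the noise;
#'   the default `NULL` leaves the noise white. White noise has a flat
#'   spectrum up to 300 Hz (and beyond), and makes the simulation resemble
#'   a high-pass filtered recording, which is the reference the rendered
#'   output is meant to be compared against.
#' @param ar_rho AR(1) channel-correlation coefficient of the synthetic
#'   unwhitening matrix (default 0.5).
#' @param gain Final scaling before int16 conversion (default 200).
#' @param seed RNG seed.
#' @return A [recording_handle()] for the rendered file (with attributes
#'   `truth_path`, `probe_path`).
#' @export
render_recording <- function(bank, truth, profile, geom, path, fs = 30000,
                             noise_sd = 0.76, noise_lowpass = NULL,
                             ar_rho = 0.5, gain = 200, seed = 1) {
  set.seed(seed)
  nch <- geom$n_channels
  n_samples <- round(truth$duration_s * fs)
  n_t <- bank$n_t
  c0 <- floor(n_t / 2)
  yr <- range(geom$y)
  chan_rel <- (geom$y - yr[1]) / max(1, diff(yr))
  # synthetic unwhitening matrix: sqrt of an AR(1) correlation matrix
  Sig <- ar_rho^abs(outer(seq_len(nch), seq_len(nch), "-"))
  es <- eigen(Sig, symmetric = TRUE)
  Un <- es$vectors %*% (sqrt(pmax(es$values, 0)) * t(es$vectors))
  chunk <- 600000
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  lo <- 0
  while (lo < n_samples) {
    hi <- min(n_samples, lo + chunk)
    n <- hi - lo
    X <- matrix(0, nch, n)
    # spikes whose waveforms touch this chunk, in three interleaved parts
    for (u in seq_len(nrow(truth$units))) {
      st <- truth$trains[[u]]
      smp <- round(st * fs)
      sel <- which(smp + n_t > lo & smp - n_t < hi)
      if (!length(sel)) next
      nrm <- truth$units$norm[u]
      bu <- truth$units$bank_unit[u]
      # drift evaluated at the unit's probe position, per time bin
      u_rel <- (bank$units[[bu]]$y - yr[1]) / max(1, diff(yr))
      dbin <- apply(profile$trace, 1, function(row)
        stats::approx(profile$positions, row, xout = u_rel, rule = 2)$y)
      nbp <- nrow(profile$trace)
      Wcache <- list()
      for (part in 0:2) {
        for (ii in sel[sel %% 3 == part]) {
          t0 <- smp[ii]
          bin <- min(nbp, max(1, floor(st[ii] / profile$bin_s) + 1))
          key <- as.character(bin)
          if (is.null(Wcache[[key]]))
            Wcache[[key]] <- bank_waveform(bank, bu, dbin[bin])
          W <- Wcache[[key]] * nrm
          cols <- (t0 - c0):(t0 - c0 + n_t - 1) - lo + 1
          ok <- cols >= 1 & cols <= n
          X[, cols[ok]] <- X[, cols[ok]] + W[, ok, drop = FALSE]
        }
      }
    }
    if (noise_sd > 0) {
      N <- matrix(rnorm(nch * n, sd = noise_sd), nch, n)
      if (!is.null(noise_lowpass)) {
        N <- lowpass_rows(N, noise_lowpass, fs)
        N <- N / sqrt(mean(N^2)) * noise_sd
      }
      X <- X + N
    }
    X <- Un %*% X
    v <- pmin(32767, pmax(-32767, round(as.vector(X) * gain)))
    writeBin(as.integer(v), con, size = 2L)
    lo <- hi
  }
  close(con); on.exit(NULL)
  truth_path <- paste0(path, ".truth.json")
  depths <- vapply(seq_len(nrow(truth$units)), function(u)
    bank$units[[truth$units$bank_unit[u]]]$y, numeric(1))
  jsonlite::write_json(
    list(fs = fs, n_channels = nch, gain = gain, ar_rho = ar_rho,
         noise_sd = noise_sd, drift_kind = profile$kind,
         units = lapply(seq_len(nrow(truth$units)), function(u)
           list(unit = u, class = truth$units$class[u],
                norm = truth$units$norm[u], y = depths[u],
                x = bank$units[[truth$units$bank_unit[u]]]$x,
                samples = round(truth$trains[[u]] * fs)))),
    truth_path, auto_unbox = TRUE, digits = NA)
  probe_path <- paste0(path, ".probe.json")
  write_probe(geom, probe_path)
  rec <- recording_handle(path, nch, fs, "int16")
  attr(rec, "truth_path") <- truth_path
  attr(rec, "probe_path") <- probe_path
  rec
}

# brick-wall low-pass of each row via FFT
lowpass_rows <- function(X, cutoff, fs) {
  n <- ncol(X)
  f <- (0:(n - 1)) / n * fs
  f <- pmin(f, fs - f)
  H <- as.numeric(f <= cutoff)
  t(Re(stats::mvfft(stats::mvfft(t(X)) * H, inverse = TRUE)) / n)
}

#' Read a ground-truth sidecar
#' @param path `.truth.json` path.
#' @return List with `fs`, `units` tibble and `trains` (sample indices).
#' @export
read_truth <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  units <- tibble::as_tibble(j$units[, c("unit", "class", "norm", "x", "y")])
  trains <- j$units$samples
  if (!is.list(trains)) trains <- list(trains)
  list(fs = j$fs, units = units, trains = trains, meta = j)
}

#' Insert hybrid ground-truth units into an existing recording
#'
#' Re-inserts the average waveforms of eligible sorted units (ACG
#' contamination < 0.1) `site_offset` sites above or below their original
#' position, with exponential ISIs (mean 500 ms) modulated by the local
#' firing rate -- computed in 100-ms bins per channel, smoothed across
#' channels with a Gaussian s.d. of 10 channels and normalized to mean 1 --
#' under an absolute 2-ms refractory floor.
#'
#' @param rec A [recording_handle()] for the base recording.
#' @param geom A [probe_geometry()].
#' @param sorted_units List of units: `times` (seconds), `waveform`
#'   (channels x n_t), `contamination` (ACG R12).
#' @param path Output path for the hybrid binary.
#' @param n_insert Number of units to insert (default 100; all eligible if
#'   fewer, with a warning).
#' @param site_offset Sites above/below (default 8).
#' @param mean_isi Mean ISI, seconds (default 0.5).
#' @param modulation Optional per-unit rate-modulation functions; `NULL`
#'   computes them from the sorted units' local firing rates.
#' @param seed RNG seed.
#' @return List with `rec` (handle to the hybrid file) and `truth`
#'   (tibble: unit, times list, offset channels).
#' @export
hybrid_insert <- function(rec, geom, sorted_units, path, n_insert = 100,
                          site_offset = 8, mean_isi = 0.5,
                          modulation = NULL, seed = 1) {
  set.seed(seed)
  elig <- which(vapply(sorted_units, function(u)
    (u$contamination %||% 0) < 0.1, logical(1)))
  if (length(elig) < n_insert) {
    if (length(elig) < n_insert && n_insert != length(elig))
      warning("only ", length(elig), " eligible units; using all")
    n_insert <- length(elig)
  }
  pick <- sample(elig, n_insert)
  dur <- rec$n_samples / rec$sampling_rate
  nch <- geom$n_channels
  # local firing rate per channel in 100-ms bins, smoothed across channels
  nb <- ceiling(dur / 0.1)
  ratemap <- matrix(0, nch, nb)
  for (u in sorted_units) {
    bc <- template_best_channel(u$waveform)
    bins <- pmin(nb, floor(u$times / 0.1) + 1)
    tb <- tabulate(bins, nbins = nb)
    ratemap[bc, ] <- ratemap[bc, ] + tb
  }
  ratemap <- apply(ratemap, 2, gauss_smooth, sigma = 10)
  if (is.null(dim(ratemap))) ratemap <- matrix(ratemap, nrow = nch)
  truth_times <- list(); offs <- integer(0)
  inserted <- list()
  for (q in seq_along(pick)) {
    u <- sorted_units[[pick[q]]]
    off <- sample(c(-site_offset, site_offset), 1)
    bc <- template_best_channel(u$waveform)
    nbc <- min(max(bc + off, 1), nch)
    mod <- if (!is.null(modulation)) {
      rep_len(if (is.list(modulation)) modulation[[q]] else modulation, nb)
    } else {
      mm <- ratemap[nbc, ]
      if (mean(mm) > 0) mm / mean(mm) else rep(1, nb)
    }
    # exponential ISIs scaled by the inverse local rate, 2-ms floor
    tcur <- runif(1, 0, mean_isi)
    times <- numeric(0)
    while (tcur < dur) {
      m <- mod[min(nb, floor(tcur / 0.1) + 1)]
      isi <- max(0.002, rexp(1, 1 / mean_isi) / max(m, 1e-6))
      tcur <- tcur + isi
      if (tcur < dur) times <- c(times, tcur)
    }
    # shift the waveform by `off` sites
    W <- matrix(0, nch, ncol(u$waveform))
    src <- seq_len(nch) - off
    ok <- src >= 1 & src <= nch
    W[ok, ] <- u$waveform[src[ok], ]
    truth_times[[q]] <- times
    offs <- c(offs, off)
    inserted[[q]] <- list(times = times, W = W)
  }
  # stream base recording and add inserted spikes
  n_t <- ncol(sorted_units[[1]]$waveform)
  c0 <- floor(n_t / 2)
  chunk <- 600000
  con <- file(path, "wb")
  on.exit(close(con))
  lo <- 0
  while (lo < rec$n_samples) {
    hi <- min(rec$n_samples, lo + chunk)
    X <- read_samples(rec, lo, hi - lo)[geom$channel_map + 1L, , drop = FALSE]
    for (ins in inserted) {
      smp <- round(ins$times * rec$sampling_rate)
      sel <- which(smp + n_t > lo & smp - n_t < hi)
      for (ii in sel) {
        cols <- (smp[ii] - c0):(smp[ii] - c0 + n_t - 1) - lo + 1
        ok <- cols >= 1 & cols <= ncol(X)
        X[, cols[ok]] <- X[, cols[ok]] + ins$W[, ok, drop = FALSE]
      }
    }
    v <- pmin(32767, pmax(-32767, round(as.vector(X))))
    writeBin(as.integer(v), con, size = 2L)
    lo <- hi
  }
  out <- recording_handle(path, nch, rec$sampling_rate, "int16")
  list(rec = out,
       truth = tibble::tibble(unit = seq_along(pick),
                              source = pick, offset = offs,
                              times = truth_times))
}


# Diverse biphasic/triphasic unit waveform: skewed Gaussian trough,
# rebound at the trough-to-peak delay, optional positive pre-deflection.
unit_wave <- function(n_t, width, rebound, t2p, skew = 1, prepk = 0,
                      pre_t = -5) {
  c0 <- floor(n_t / 2)
  tt <- (0:(n_t - 1)) - c0
  w_side <- ifelse(tt < 0, width, width * skew)
  w <- -exp(-tt^2 / (2 * w_side^2)) +
    rebound * exp(-(tt - t2p)^2 / (2 * pmin(0.5 * t2p, 8)^2)) +
    prepk * exp(-(tt - pre_t)^2 / (2 * (0.8 * width)^2))
  w / sqrt(sum(w^2))
}
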