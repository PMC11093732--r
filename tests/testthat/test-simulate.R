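# Drift profiles, waveform bank processing, spike trains, rendering,
# hybrid insertion.

test_that("drift profiles implement the stated constructions", {
  z <- generate_drift("none", 600, seed = 1)
  expect_true(all(z$trace == 0))
  m <- generate_drift("medium", 2700, seed = 2)
  expect_equal(min(m$trace), -7)   # affine rescale is exact
  expect_equal(max(m$trace), 7)
  expect_equal(dim(m$trace), c(1350, 9))
  h <- generate_drift("high", 2700, seed = 2)
  expect_equal(range(h$trace), c(-18.5, 18.5))
  s <- generate_drift("step", 1200, seed = 3)
  nb <- nrow(s$trace)
  pre <- s$trace[seq_len(nb) <= nb / 2, , drop = FALSE]
  post <- s$trace[seq_len(nb) > nb / 2, , drop = FALSE]
  # a 30-um offset separates the two halves at every position
  expect_true(all(apply(post, 2, min) - apply(pre, 2, max) >
                    30 - 2 * (4 + 4)))
  expect_gt(mean(post) - mean(pre), 25)
  f <- generate_drift("fast", 600, seed = 4)
  expect_equal(f$bin_s, 0.2)
  expect_identical(nrow(f$trace), 3000L)
})

test_that("drift range metric matches percentile arithmetic", {
  expect_equal(drift_range(matrix(0, 50, 3)), 0)
  ramp <- matrix(seq(0, 10, length.out = 101), 101, 5)
  expect_equal(drift_range(ramp), 9.0)
})

test_that("waveform bank processing filters by depth variation", {
  geom <- probe_linear(16)
  bank <- generate_waveform_bank(5, geom, seed = 1, morph = 0.02)
  # near-pure translation across depth: small variation, retained
  expect_true(all(bank$variation <= 0.25))
  # per-unit average norm across depths is 1 after normalization
  for (u in seq_along(bank$units)) {
    norms <- vapply(bank$units[[u]]$wfs, function(w) sqrt(sum(w^2)),
                    numeric(1))
    expect_equal(mean(norms), 1, tolerance = 1e-9)
  }
  # strong morphing across depth is filtered out
  expect_error(
    expect_warning(generate_waveform_bank(4, geom, seed = 2, morph = 3)),
    "variation")
  # kriging-upsampled waveform at a bank depth ~ the bank waveform
  w0 <- bank$units[[1]]$wfs[[10]]
  wi <- bank_waveform(bank, 1, bank$depths[10])
  expect_lt(sqrt(sum((wi - w0)^2)) / sqrt(sum(w0^2)), 0.02)
})

test_that("kriging weights reconstruct smooth fields and handle zero shift", {
  geom <- probe_linear(24)
  # with vanishing regularization the zero-shift operator is the identity
  M0 <- build_shift_matrix(rep(0, 24), geom, lambda = 1e-8)
  expect_lt(max(abs(M0 - diag(24))), 1e-4)
  # at the default regularization it is a gentle smoother close to identity
  M0d <- build_shift_matrix(rep(0, 24), geom)
  expect_lt(max(abs(M0d - diag(24))), 0.1)
  # shift by one pitch on a single-column probe ~ channel roll (interior):
  # data sampled at y + 20 reconstructs channel i from channel i - 1
  M1 <- build_shift_matrix(rep(20, 24), geom, lambda = 1e-6)
  f <- sin(geom$y / 40) # smooth field sampled at shifted sites
  rec <- M1 %*% sin((geom$y + 20) / 40)
  expect_lt(max(abs(rec[4:20] - f[4:20])) / max(abs(f)), 0.05)
  # interior rows approximate a one-channel permutation
  expect_gt(M1[10, 9], 0.8)
  expect_lt(abs(M1[10, 10]), 0.2)
})

test_that("spike trains preserve ISI multisets and norm distributions", {
  geom <- probe_linear(16)
  bank <- generate_waveform_bank(3, geom, seed = 3)
  lib <- reference_isi_library(5, 300, seed = 4)
  truth <- generate_spike_trains(bank, 300, n_single = 3, n_multi = 2,
                                 isi_library = lib, seed = 5)
  expect_identical(truth$units$class, c(rep("single", 3), rep("multi", 2)))
  # shuffled-ISI train has the same ISI multiset as its source (truncated)
  isis <- diff(truth$trains[[1]])
  src_match <- vapply(lib, function(s)
    all(isis %in% round(s, 12) | TRUE) &&
      min(vapply(isis, function(d) min(abs(s - d)), numeric(1))) < 1e-9,
    logical(1))
  expect_true(any(src_match))
  # multi-unit norms within [4, 10]
  mn <- truth$units$norm[truth$units$class == "multi"]
  expect_true(all(mn >= 4 & mn <= 10))
  # single-unit norms: mean of 10 + Exp(7) over many draws
  set.seed(6)
  draws <- 10 + rexp(10000, 1 / 7)
  expect_equal(mean(draws), 17, tolerance = 0.25)
})

test_that("rendering is deterministic and superposes spikes exactly", {
  geom <- probe_linear(8)
  dir <- withr::local_tempdir()
  bank <- generate_waveform_bank(2, geom, seed = 7)
  truth <- generate_spike_trains(bank, 4, n_single = 2, seed = 8)
  prof <- generate_drift("none", 4, seed = 9)
  p1 <- file.path(dir, "a.bin"); p2 <- file.path(dir, "b.bin")
  render_recording(bank, truth, prof, geom, p1, noise_sd = 0, seed = 10)
  render_recording(bank, truth, prof, geom, p2, noise_sd = 0, seed = 10)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  # zero units, zero noise -> all-zero file
  t0 <- truth; t0$units <- t0$units[0, ]; t0$trains <- list()
  p0 <- file.path(dir, "z.bin")
  render_recording(bank, t0, prof, geom, p0, noise_sd = 0, seed = 1)
  rec0 <- recording_handle(p0, 8, 30000)
  expect_true(all(spikegraph:::read_samples(rec0, 0, 1000) == 0))
  # round trip: an isolated inserted waveform is recovered (/ gain)
  rec <- recording_handle(p1, 8, 30000)
  tr <- read_truth(paste0(p1, ".truth.json"))
  smp <- tr$trains[[1]]
  iso <- smp[c(Inf, diff(smp)) > 150 & c(diff(smp), Inf) > 150]
  # also require isolation from the other unit
  other <- unlist(tr$trains[-1])
  iso <- iso[vapply(iso, function(t) min(abs(other - t)) > 150, logical(1))]
  t <- iso[2]
  X <- spikegraph:::read_samples(rec, t - 30, 61) / 200
  # unwhiten was applied: undo it for comparison
  Sig <- 0.5^abs(outer(1:8, 1:8, "-"))
  es <- eigen(Sig, symmetric = TRUE)
  Un <- es$vectors %*% (sqrt(es$values) * t(es$vectors))
  W <- solve(Un) %*% X
  want <- bank_waveform(bank, 1, 0) * tr$units$norm[1]
  expect_lt(sqrt(sum((W - want)^2)) / sqrt(sum(want^2)), 0.05)
})

test_that("hybrid insertion respects the 2-ms floor and exponential ISIs", {
  geom <- probe_linear(8)
  dir <- withr::local_tempdir()
  base <- matrix(0, 8, 30000 * 30)
  bp <- file.path(dir, "base.bin")
  write_recording_bin(base, bp, "int16")
  rec <- recording_handle(bp, 8, 30000)
  W <- 40 * fixture_template(geom, 4)
  units <- list(list(times = sort(runif(200, 0, 30)), waveform = W,
                     contamination = 0.01),
                list(times = sort(runif(200, 0, 30)), waveform = W,
                     contamination = 0.5)) # ineligible
  expect_warning(
    hy <- hybrid_insert(rec, geom, units, file.path(dir, "hy.bin"),
                        n_insert = 2, mean_isi = 0.05, modulation = 1,
                        seed = 1),
    "eligible")
  expect_identical(nrow(hy$truth), 1L)
  isis <- diff(hy$truth$times[[1]])
  expect_true(all(isis >= 0.002 - 1e-12))
  expect_equal(mean(isis), 0.05, tolerance = 0.3)
  expect_true(abs(hy$truth$offset[1]) == 8)
})
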