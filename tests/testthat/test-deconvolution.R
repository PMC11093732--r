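# Simple-template bank, detection, template learning, matching pursuit,
# and background-subtracted features.

test_that("simple-template combinatorics match the probe layouts", {
  bank <- build_simple_templates(probe_np1(), default_shapes())
  expect_identical(nrow(bank$positions), 1536L)
  expect_identical(bank$n_templates, 46080L)
  toy <- build_simple_templates(probe_linear(4), default_shapes())
  expect_identical(nrow(toy$positions), 16L)
  expect_identical(toy$n_templates, 480L)
  # footprints and shapes are separately unit-norm
  expect_equal(rowSums(toy$footprints[[3]]^2), rep(1, 16))
  expect_equal(colSums(toy$shapes^2), rep(1, 6), ignore_attr = TRUE)
})

test_that("variance explained identities hold", {
  geom <- probe_linear(8)
  W <- fixture_template(geom, 4)
  expect_equal(variance_explained_simple(W, 3 * W), 9)
  # orthogonal data explains nothing
  D <- matrix(rnorm(length(W)), nrow(W))
  D <- D - sum(D * W) * W
  expect_equal(variance_explained_simple(W, D), 0, tolerance = 1e-12)
  expect_error(variance_explained_simple(2 * W, W), "unit norm")
  # grid-search oracle: (W'D)^2 == ||D||^2 - min_x ||D - xW||^2
  set.seed(1)
  D <- matrix(rnorm(length(W)), nrow(W))
  xs <- seq(-30, 30, by = 0.001)
  resid <- vapply(xs, function(x) sum((D - x * W)^2), numeric(1))
  expect_equal(variance_explained_simple(W, D),
               sum(D^2) - min(resid), tolerance = 1e-4)
  # learned-template identities: V = 2 xw W'D - xw^2 = ||D||^2-||D-xw W||^2
  xw <- 7
  expect_equal(variance_explained_learned(W, xw, xw * W), xw^2)
  expect_equal(variance_explained_learned(W, xw, 0 * W), -xw^2)
  expect_equal(variance_explained_learned(W, xw, D),
               sum(D^2) - sum((D - xw * W)^2), tolerance = 1e-9)
  expect_error(variance_explained_learned(W, -1, D), "positive")
})

test_that("universal detection finds isolated spikes of either sign only", {
  geom <- probe_linear(16)
  bank <- build_simple_templates(geom, default_shapes())
  W <- fixture_template(geom, 8, s = 2, sigma_um = 25)
  d <- matrix(0, 16, 1122)
  c0 <- 30
  d[, (561 - c0):(561 - c0 + 60)] <- 12 * W
  batch <- fixture_batch(d, N_T = 1000)
  sp <- detect_spikes_universal(batch, bank, threshold = 9)
  expect_identical(nrow(sp), 1L)
  expect_lte(abs(sp$time - (561 - 61 - 1)), 2)
  expect_lte(abs(sp$y - geom$y[8]), 10)
  # sign-inverted twin is detected through the inverted template pair
  batch$data <- -d
  sp2 <- detect_spikes_universal(batch, bank, threshold = 9)
  expect_identical(nrow(sp2), 1L)
  expect_lt(sp2$amplitude, 0)
  # sub-threshold noise yields nothing
  set.seed(2)
  batch$data <- matrix(rnorm(16 * 1122, sd = 0.2), 16)
  expect_identical(nrow(detect_spikes_universal(batch, bank, 9)), 0L)
})

test_that("two close spikes at one position yield a single detection", {
  geom <- probe_linear(16)
  bank <- build_simple_templates(geom, default_shapes())
  W <- fixture_template(geom, 8, s = 2, sigma_um = 25)
  d <- matrix(0, 16, 1122)
  c0 <- 30
  add <- function(t, a) d[, (t - c0):(t - c0 + 60)] <<-
    d[, (t - c0):(t - c0 + 60)] + a * W
  add(500, 12); add(505, 10) # 5 samples apart: inside the +/-20 window
  sp <- detect_spikes_universal(fixture_batch(d, N_T = 1000), bank, 9)
  expect_identical(nrow(sp), 1L)
  expect_lte(abs(sp$time - (500 - 61 - 1)), 2) # the larger one wins
})

test_that("detection threshold sweep is monotone", {
  geom <- probe_linear(16)
  bank <- build_simple_templates(geom, default_shapes())
  set.seed(3)
  d <- matrix(rnorm(16 * 1122, sd = 0.5), 16, 1122)
  for (ch in c(3, 8, 13)) {
    W <- fixture_template(geom, ch, s = sample(6, 1))
    t <- sample(300:900, 1)
    d[, (t - 30):(t + 30)] <- d[, (t - 30):(t + 30)] + runif(1, 10, 20) * W
  }
  batch <- fixture_batch(d, N_T = 1000)
  prev <- NULL
  for (thr in c(6, 9, 12, 15)) {
    sp <- detect_spikes_universal(batch, bank, thr)
    if (!is.null(prev)) expect_true(all(sp$time %in% prev$time))
    prev <- sp
  }
})

test_that("spike positions come from nonnegative projection centers of mass", {
  expect_equal(spike_xy(c(0, 5, 0), c(0, 0, 0), c(0, 20, 40)), c(0, 20))
  expect_equal(spike_xy(c(3, 3), c(0, 0), c(0, 20)), c(0, 10))
  expect_equal(spike_xy(c(-1, -2), c(0, 4), c(0, 20)), c(4, 20))
  # Gaussian footprint centered between channels
  y <- seq(0, 140, by = 20)
  w <- exp(-(y - 50)^2 / (2 * 25^2))
  got <- spike_xy(w, rep(0, 8), y)
  expect_lt(abs(got[2] - 50), 2)
})

test_that("shape learning recovers distinct waveforms and an orthonormal basis", {
  set.seed(4)
  n_t <- 61
  s1 <- proto_wave_for_tests(n_t, 2, 0.3)
  s2 <- proto_wave_for_tests(n_t, 5, 0.6)
  # synthesize a recording whose spikes are pure s1/s2 on single channels
  geom <- probe_linear(4)
  d <- matrix(rnorm(4 * 60000, sd = 0.05), 4, 60000)
  for (i in 1:300) {
    ch <- sample(4, 1); t <- sample(seq(200, 59800, by = 180), 1)
    s <- if (i %% 2) s1 else s2
    d[ch, (t - 30):(t + 30)] <- d[ch, (t - 30):(t + 30)] + 14 * s
  }
  rec <- fixture_recording(d, scale = 100)
  kernel <- build_highpass_kernel(300, 60000, 30000)
  model <- fit_whitening(rec, geom, kernel = kernel)
  out <- learn_shapes_and_pcs(rec, geom, model, kernel, max_batches = 1,
                              threshold = 5)
  expect_equal(crossprod(out$basis), diag(6), tolerance = 1e-6)
  # centroids match the *observable* (high-passed) shapes: compare against
  # the prototypes run through the same filter
  bw <- signal::butter(3, 300 / 15000, type = "high")
  filt <- function(s) {
    f <- as.numeric(signal::filter(bw, c(s, numeric(80))))[seq_along(s) + 10]
    f <- as.numeric(signal::filter(bw, c(numeric(10), s, numeric(70))))[
      seq_along(s) + 10]
    f / sqrt(sum(f^2))
  }
  truth_f <- cbind(filt(s1), filt(s2))
  # cosine at the best alignment: trough re-centering jitters +/- a couple
  # of samples, which smears but does not change the shape
  lag_cos <- function(a, b) max(vapply(-5:5, function(l) {
    ia <- max(1, 1 + l):min(length(a), length(a) + l)
    abs(sum(a[ia] * b[ia - l])) /
      sqrt(sum(a[ia]^2) * sum(b[ia - l]^2))
  }, numeric(1)))
  best <- vapply(1:2, function(j)
    max(vapply(seq_len(ncol(out$shapes)), function(i)
      lag_cos(out$shapes[, i], truth_f[, j]), numeric(1))), numeric(1))
  expect_gt(min(best), 0.9)
  # too few snippets falls back to prototypes with a warning
  quiet <- matrix(rnorm(4 * 6000, sd = 0.01), 4)
  rec2 <- fixture_recording(quiet, scale = 100)
  expect_warning(
    out2 <- learn_shapes_and_pcs(rec2, geom, model,
                                 build_highpass_kernel(300, 6000, 30000),
                                 N_T = 6000, max_batches = 1),
    "prototypes")
  expect_equal(out2$shapes, default_shapes())
})

test_that("matching pursuit resolves overlapping spikes exactly", {
  set.seed(5)
  geom <- probe_linear(16)
  basis <- pc_basis_for_tests()
  W1 <- fixture_template(geom, 5, s = 1, sigma_um = 30)
  W2 <- fixture_template(geom, 10, s = 4, sigma_um = 25)
  tl <- learned_templates_for_tests(list(W1, W2), c(12, 15), geom, basis)
  d <- matrix(0, 16, 1122)
  c0 <- 30
  put <- function(W, t, a) d[, (61 + t - c0):(61 + t - c0 + 60)] <<-
    d[, (61 + t - c0):(61 + t - c0 + 60)] + a * W
  put(W1, 300, 12); put(W2, 303, 15) # temporal collision across channels
  put(W1, 700, 12)
  mp <- matching_pursuit(fixture_batch(d, N_T = 1000), tl, threshold = 8)
  expect_identical(nrow(mp$spikes), 3L)
  expect_setequal(mp$spikes$template_id, c(1L, 2L, 1L))
  expect_true(all(abs(sort(mp$spikes$time) - c(299, 302, 699)) <= 1))
  # reconstruction: data = sum of accepted spikes + residual (~0 here)
  expect_lt(sqrt(sum(mp$residual$data^2)), 1e-9)
  # exactly one template instance at amplitude x_W: residual ~ 0
  d2 <- matrix(0, 16, 1122)
  d2[, (61 + 500 - c0):(61 + 500 - c0 + 60)] <- 12 * W1
  mp2 <- matching_pursuit(fixture_batch(d2, N_T = 1000), tl, 8)
  expect_identical(nrow(mp2$spikes), 1L)
  expect_lt(sqrt(sum(mp2$residual$data^2)), 1e-9)
})

test_that("matching pursuit never increases the residual norm", {
  set.seed(6)
  geom <- probe_linear(16)
  basis <- pc_basis_for_tests()
  W1 <- fixture_template(geom, 5, s = 1)
  W2 <- fixture_template(geom, 10, s = 3)
  tl <- learned_templates_for_tests(list(W1, W2), c(12, 14), geom, basis)
  d <- matrix(rnorm(16 * 1122, sd = 0.4), 16, 1122)
  for (t in seq(200, 900, by = 70))
    d[, (61 + t - 30):(61 + t + 30)] <- d[, (61 + t - 30):(61 + t + 30)] +
      sample(c(11, 13, 15), 1) * (if (t %% 140 < 70) W1 else W2)
  before <- sum(d^2)
  mp <- matching_pursuit(fixture_batch(d, N_T = 1000), tl, 8)
  expect_gt(nrow(mp$spikes), 0)
  expect_lte(sum(mp$residual$data^2), before)
  # reconstruction property to round-off
  recon <- mp$residual$data
  c0 <- 30
  for (i in seq_len(nrow(mp$spikes))) {
    k <- mp$spikes$template_id[i]; t <- mp$spikes$t_local[i]
    recon[, (t - c0):(t - c0 + 60)] <- recon[, (t - c0):(t - c0 + 60)] +
      tl$x_W[k] * tl$waveforms[[k]]
  }
  expect_equal(recon, d, tolerance = 1e-9)
})

test_that("rank-3 factors explain template variance", {
  geom <- probe_linear(16)
  basis <- pc_basis_for_tests()
  set.seed(7)
  # realistic templates: a few separable spatial x temporal components
  wfs <- lapply(c(3, 8, 13), function(ch) {
    W <- fixture_template(geom, ch, s = 1) +
      0.3 * fixture_template(geom, min(ch + 2, 16), s = 4) +
      0.1 * fixture_template(geom, max(ch - 1, 1), s = 5)
    W / sqrt(sum(W^2))
  })
  tl <- learned_templates_for_tests(wfs, c(10, 12, 14), geom, basis)
  expect_true(all(tl$rank3_varexp >= 0.95))
  for (k in 1:3) {
    recon <- tl$spatial[[k]] %*% t(tl$temporal[[k]])
    expect_gt(1 - sum((recon - tl$waveforms[[k]])^2), 0.95)
  }
})

test_that("features with background subtraction remove overlap contamination", {
  geom <- probe_linear(16)
  basis <- pc_basis_for_tests()
  W1 <- fixture_template(geom, 5, s = 1, sigma_um = 30)
  W2 <- fixture_template(geom, 8, s = 4, sigma_um = 30) # nearby: overlaps
  tl <- learned_templates_for_tests(list(W1, W2), c(12, 15), geom, basis)
  d <- matrix(0, 16, 1122)
  c0 <- 30
  put <- function(W, t, a) d[, (61 + t - c0):(61 + t - c0 + 60)] <<-
    d[, (61 + t - c0):(61 + t - c0 + 60)] + a * W
  put(W1, 300, 12); put(W2, 302, 15)
  put(W1, 700, 12)                 # isolated reference
  mp <- matching_pursuit(fixture_batch(d, N_T = 1000), tl, 8)
  spk <- features_with_background_subtraction(mp$residual, mp$spikes, tl,
                                              basis)
  i_col <- which(spk$template_id == 1 & spk$time < 500)
  i_iso <- which(spk$template_id == 1 & spk$time > 500)
  f_col <- spk$feat[[i_col]]; f_iso <- spk$feat[[i_iso]]
  expect_lt(sqrt(sum((f_col - f_iso)^2)) / sqrt(sum(f_iso^2)), 0.1)
  # naive raw-patch features (residual + ALL spikes added back) are
  # contaminated by the overlapping unit
  t <- spk$t_local[i_col]
  ch <- spk$chans[[i_col]]
  raw_patch <- d[ch, (t - c0):(t - c0 + 60)]
  f_naive <- raw_patch %*% basis
  expect_gt(sqrt(sum((f_naive - f_iso)^2)) / sqrt(sum(f_iso^2)), 0.2)
  # zero-amplitude template contribution leaves pure residual projections
  tl0 <- tl; tl0$x_W <- c(1e-9, 1e-9)
  spk0 <- features_with_background_subtraction(mp$residual, mp$spikes, tl0,
                                               basis)
  resid_proj <- mp$residual$data[spk0$chans[[i_iso]],
                                 (spk0$t_local[i_iso] - c0):
                                   (spk0$t_local[i_iso] - c0 + 60)] %*% basis
  expect_equal(spk0$feat[[i_iso]], resid_proj, tolerance = 1e-6)
})
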