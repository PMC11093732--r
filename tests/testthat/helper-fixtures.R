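# Shared fixtures, built in code at test time.

fixture_probe16 <- function() probe_linear(16)

# Write a small float-valued matrix as an int16 recording and return the
# handle (values are scaled to keep int16 rounding loss negligible).
fixture_recording <- function(data, dir = NULL, fs = 30000, scale = 1) {
  if (is.null(dir)) {
    dir <- tempfile("spikegraph_fix")
    dir.create(dir)
  }
  path <- file.path(dir, "fix.bin")
  write_recording_bin(data * scale, path, "int16")
  recording_handle(path, nrow(data), fs, "int16")
}

# A unit-norm spatiotemporal template on a probe: Gaussian footprint
# centered on channel `ch` times prototype shape `s`.
fixture_template <- function(geom, ch, s = 1, sigma_um = 30, n_t = 61) {
  shapes <- default_shapes(n_t)
  amp <- exp(-((geom$x - geom$x[ch])^2 + (geom$y - geom$y[ch])^2) /
               (2 * sigma_um^2))
  W <- outer(amp, shapes[, s])
  W / sqrt(sum(W^2))
}

# A padded batch wrapping a bare matrix.
fixture_batch <- function(data, N_T = ncol(data) - 122, n_t = 61, t0 = 0) {
  structure(list(data = data, batch_index = 0L, N_T = as.integer(N_T),
                 n_t = as.integer(n_t), t0 = t0),
            class = "padded_batch")
}

# Spike train with an absolute refractory period (gamma ISIs + floor).
fixture_refractory_train <- function(rate_hz, duration_s, refractory_s = 0.003,
                                     seed = 1) {
  set.seed(seed)
  n <- round(rate_hz * duration_s * 1.5) + 10
  isi <- rexp(n, rate_hz) + refractory_s
  st <- cumsum(isi)
  st[st < duration_s]
}

# Small rendered simulation shared across drift / end-to-end style tests.
# Cached per session to keep the suite fast.
fixture_simulation <- function(kind = "none", minutes = 2, n_units = 6,
                               seed = 2) {
  key <- sprintf("sim_%s_%s_%d_%d", kind, gsub("[.]", "p", minutes), n_units, seed)
  cache <- Sys.getenv("SPIKEGRAPH_TEST_CACHE", tempdir())
  path <- file.path(cache, paste0(key, ".bin"))
  geom <- probe_linear(16)
  bank <- generate_waveform_bank(n_units, geom, seed = seed)
  truth <- generate_spike_trains(bank, minutes * 60, n_single = n_units,
                                 min_norm = 12, seed = seed + 1)
  prof <- generate_drift(kind, minutes * 60, seed = seed + 2)
  if (!file.exists(path)) {
    render_recording(bank, truth, prof, geom, path, seed = seed + 3)
  }
  list(rec = recording_handle(path, geom$n_channels, 30000),
       geom = geom, bank = bank, truth = truth, profile = prof)
}

# Thin wrappers over internals used as test oracles/builders.
proto_wave_for_tests <- function(n_t, width, rebound)
  spikegraph:::proto_wave(n_t, width, rebound)

pc_basis_for_tests <- function(n_t = 61)
  spikegraph:::default_pc_basis(n_t)

learned_templates_for_tests <- function(wfs, x_W, geom, basis)
  spikegraph:::build_learned_templates(wfs, x_W, rep(100, length(wfs)),
                                       geom, basis)
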