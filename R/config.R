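#' Run configuration
#'
#' All tunable parameters of the pipeline in one declarative list. Every
#' run writes the resolved configuration next to its outputs for
#' provenance. Ablation switches mirror the pipeline stages: drift
#' correction, rigid-only registration, deconvolution, reclustering, the
#' correlogram criterion, and feature background subtraction.
#'
#' @param ... Named overrides of the defaults.
#' @return A named list of class `spikegraph_config`.
#' @export
spikegraph_config <- function(...) {
  cfg <- list(
    # batching
    N_T = 60000L,            # batch size, samples
    n_t = 61L,               # waveform length / pad, samples
    gain = 1.0,              # multiplicative gain applied at load
    # preprocessing
    highpass_hz = 300,       # high-pass cutoff
    butter_order = 3L,       # Butterworth reference order (forward pass)
    whiten_neighbors = 32L,  # ZCA neighborhood, channels
    whiten_epsilon = NULL,   # NULL = 1e-6 * mean(S)
    # drift
    do_drift_correction = TRUE,
    rigid_only = FALSE,
    n_blocks = 6L,
    drift_bin_s = 2,
    kriging_sigma = 20,      # um
    kriging_lambda = 0.01,
    # detection / deconvolution
    threshold_universal = 9, # simple-template threshold, norm units
    threshold_learned = 8,   # matching-pursuit threshold, norm units
    n_shapes = 6L,
    shapes_from_data = FALSE, # default: packaged prototype shapes/PCs
    n_sizes = 5L,
    n_pcs = 6L,
    do_deconv = TRUE,
    do_feature_deconv = TRUE,
    mp_rounds = 50L,
    # clustering
    section_um = 40,
    n_sub = 25000L,
    knn_k = 10L,
    n_init = 200L,
    cluster_iter = 30L,
    do_recluster = TRUE,
    # curation
    do_ccg = TRUE,
    ccg_censor_bins = 2L, # central CCG bins censored by deconvolution
                          # (the +/-n_t exclusion is 2.03 ms: bins 0-1 are
                          # fully dead, bin 2 partially; bin 3 onward is
                          # fully observable)
    bimod_threshold = 0.5,
    modularity_threshold = 0.2,
    sim_threshold = 0.5,
    good_threshold = 0.2,
    seed = 1L)
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(cfg))
    if (length(bad)) stop("unknown config fields: ",
                          paste(bad, collapse = ", "))
    cfg[names(ov)] <- ov
  }
  structure(cfg, class = c("spikegraph_config", "list"))
}

#' Read / write a configuration as YAML
#' @param path YAML file path.
#' @export
read_config <- function(path) {
  do.call(spikegraph_config, yaml::read_yaml(path) %||% list())
}

#' @rdname read_config
#' @param cfg A [spikegraph_config()].
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
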