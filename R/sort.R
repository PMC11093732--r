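#' Sort a recording end to end
#'
#' The full pipeline: whitening fit, simple-template bank, drift estimation
#' and per-batch alignment operators, template learning (clustering of
#' simple-template detections), rank-3 matching pursuit with learned
#' templates, background-subtracted PC features, per-section graph
#' clustering with merge-tree curation, global merges, and good/mua
#' labeling.
#'
#' @param rec A [recording_handle()].
#' @param geom A [probe_geometry()].
#' @param config A [spikegraph_config()].
#' @param out_dir Optional output directory for Phy-compatible files and
#'   the resolved configuration.
#' @param verbose Print stage progress.
#' @return A `spikegraph_sort` object: `spikes` (tibble with final cluster
#'   labels), `units` (per-unit tibble: id, n_spikes, position, group,
#'   contamination), `templates`, `drift`, `config`, `audit`.
#' @export
sort_recording <- function(rec, geom, config = spikegraph_config(),
                           out_dir = NULL, verbose = interactive()) {
  cfg <- config
  say <- function(...) if (verbose) message(sprintf(...))
  fs <- rec$sampling_rate
  kernel <- build_highpass_kernel(cfg$highpass_hz, cfg$N_T, fs,
                                  cfg$butter_order)
  say("fitting whitening model")
  model <- fit_whitening(rec, geom, cfg$whiten_neighbors,
                         cfg$whiten_epsilon, kernel, cfg$N_T, cfg$n_t)
  sp <- if (cfg$shapes_from_data) {
    learn_shapes_and_pcs(rec, geom, model, kernel, cfg$n_t, N_T = cfg$N_T)
  } else {
    list(shapes = default_shapes(cfg$n_t, cfg$n_shapes),
         basis = default_pc_basis(cfg$n_t, cfg$n_pcs))
  }
  bank <- build_simple_templates(geom, sp$shapes, cfg$n_sizes)
  nb <- n_batches(rec, cfg$N_T)
  drift <- NULL
  shift_mats <- NULL
  if (cfg$do_drift_correction) {
    say("estimating drift")
    drift <- correct_drift(rec, geom, model, kernel, bank, cfg)
    shift_mats <- drift$shift_matrices
  }
  get_shift <- function(b) if (is.null(shift_mats)) NULL else
    shift_mats[[b + 1]]
  # --- template learning pass -----------------------------------------
  say("detecting spikes for template learning")
  det <- vector("list", nb)
  for (b in seq_len(nb) - 1L) {
    x <- preprocess_batch(rec, geom, b, model, kernel, get_shift(b),
                          cfg$N_T, cfg$n_t)
    s <- detect_spikes_universal(x, bank, cfg$threshold_universal)
    if (nrow(s)) {
      s <- extract_detection_features(x, s, sp$basis, geom, cfg$n_t)
      det[[b + 1]] <- s
    }
  }
  det <- dplyr::bind_rows(det)
  if (!nrow(det)) stop("no spikes detected")
  templates <- NULL
  # --- deconvolution pass ---------------------------------------------
  if (cfg$do_deconv) {
    say("learning templates from %d detections", nrow(det))
    templates <- learn_templates(det, sp$basis, geom, cfg$section_um, fs,
                                 cluster_args = list(n_sub = cfg$n_sub,
                                                     k = cfg$knn_k,
                                                     n_init = cfg$n_init,
                                                     seed = cfg$seed))
    say("matching pursuit with %d templates", length(templates$waveforms))
    allsp <- vector("list", nb)
    for (b in seq_len(nb) - 1L) {
      x <- preprocess_batch(rec, geom, b, model, kernel, get_shift(b),
                            cfg$N_T, cfg$n_t)
      mp <- matching_pursuit(x, templates, cfg$threshold_learned,
                             cfg$mp_rounds)
      if (!nrow(mp$spikes)) next
      spk <- if (cfg$do_feature_deconv) {
        features_with_background_subtraction(mp$residual, mp$spikes,
                                             templates, sp$basis)
      } else {
        # raw-patch features: add the spikes back before projecting
        raw <- mp$residual
        for (i in seq_len(nrow(mp$spikes))) {
          k <- mp$spikes$template_id[i]
          t <- mp$spikes$t_local[i]
          c0 <- floor(templates$n_t / 2)
          win <- (t - c0):(t - c0 + templates$n_t - 1)
          raw$data[, win] <- raw$data[, win] +
            templates$x_W[k] * templates$waveforms[[k]]
        }
        zero <- templates
        zero$x_W <- rep(1e-12, length(templates$x_W))
        out <- features_with_background_subtraction(raw, mp$spikes, zero,
                                                    sp$basis)
        out
      }
      allsp[[b + 1]] <- spk
    }
    spikes <- dplyr::bind_rows(allsp)
    spikes$y <- templates$positions[spikes$template_id, 2]
    spikes$x <- templates$positions[spikes$template_id, 1]
  } else {
    spikes <- det
    spikes$template_id <- spikes$pos
  }
  say("%d spikes extracted", nrow(spikes))
  # --- final clustering ------------------------------------------------
  if (cfg$do_recluster) {
    sec <- floor(spikes$y / cfg$section_um)
    labels <- integer(nrow(spikes))
    audit <- list()
    offset <- 0L
    for (s in sort(unique(sec))) {
      idx <- which(sec == s)
      if (length(idx) < 20) {
        labels[idx] <- offset + 1L
        offset <- offset + 1L
        next
      }
      U <- sort(unique(unlist(spikes$chans[idx])))
      X <- embed_features(spikes$feat[idx], spikes$chans[idx], U)
      cl <- cluster_features(X, n_sub = cfg$n_sub, k = cfg$knn_k,
                             n_init = cfg$n_init, n_iter = cfg$cluster_iter,
                             seed = cfg$seed)
      tree <- build_merge_tree(cl$graph, cl$labels)
      tv <- traverse_tree(tree, X, cl$labels,
                          spike_times = spikes$time[idx] / fs,
                          bimod_threshold = cfg$bimod_threshold,
                          modularity_threshold = cfg$modularity_threshold,
                          use_ccg = cfg$do_ccg,
                          censor_bins = cfg$ccg_censor_bins)
      labels[idx] <- offset + tv$labels
      offset <- offset + max(tv$labels)
      audit[[length(audit) + 1]] <- tv$audit
    }
    audit <- dplyr::bind_rows(audit)
  } else {
    labels <- spikes$template_id
    audit <- tibble::tibble()
  }
  spikes$cluster <- as.integer(labels)
  # --- global merges and labels ---------------------------------------
  units <- make_units(spikes, templates, fs, bank)
  if (cfg$do_ccg && length(units) > 1) {
    say("global merges over %d units", length(units))
    gm <- global_merges(units, cfg$sim_threshold,
                        censor_bins = cfg$ccg_censor_bins)
    spikes$cluster <- gm$assignment[spikes$cluster]
    units <- gm$units
  }
  groups <- vapply(units, function(u)
    label_good(u$times, cfg$good_threshold,
               censor_bins = cfg$ccg_censor_bins), character(1))
  utab <- tibble::tibble(
    cluster = seq_along(units),
    n_spikes = vapply(units, function(u) length(u$times), numeric(1)),
    group = groups,
    x = vapply(units, function(u) template_position(u$waveform, geom)[1],
               numeric(1)),
    y = vapply(units, function(u) template_position(u$waveform, geom)[2],
               numeric(1)))
  spikes <- dplyr::arrange(spikes, .data$time)
  res <- structure(list(spikes = spikes, units = utab,
                        unit_objects = units,
                        templates = templates, drift = drift,
                        config = cfg, audit = audit, fs = fs, geom = geom),
                   class = "spikegraph_sort")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_phy_output(spikes, templates, geom, out_dir,
                     groups = stats::setNames(groups, utab$cluster))
    write_config(cfg, file.path(out_dir, "spikegraph_config.yaml"))
    if (!is.null(drift)) {
      utils::write.csv(tidy.drift_trace(drift$trace),
                       file.path(out_dir, "drift_trace.csv"),
                       row.names = FALSE)
    }
  }
  res
}

# Per-spike PC features for universal detections (raw patches; no
# background subtraction available at this stage).
extract_detection_features <- function(batch, spikes, basis, geom, n_t,
                                       n_chans = 10) {
  c0 <- floor(n_t / 2)
  nch <- geom$n_channels
  n_chans <- min(n_chans, nch)
  L <- ncol(batch$data)
  feat <- vector("list", nrow(spikes)); chans <- vector("list", nrow(spikes))
  for (i in seq_len(nrow(spikes))) {
    d2 <- (geom$x - spikes$x[i])^2 + (geom$y - spikes$y[i])^2
    ch <- order(d2, seq_len(nch))[seq_len(n_chans)]
    t <- spikes$time[i] - batch$t0 + batch$n_t + 1
    win <- (t - c0):(t - c0 + n_t - 1)
    ok <- win >= 1 & win <= L
    patch <- matrix(0, n_chans, n_t)
    patch[, ok] <- batch$data[ch, win[ok], drop = FALSE]
    feat[[i]] <- patch %*% basis
    chans[[i]] <- ch
  }
  spikes$feat <- feat
  spikes$chans <- chans
  spikes
}

# Aggregate spikes into unit objects (times in seconds, mean waveform).
# The unit waveform is reconstructed from the mean of its spikes' stored
# PC features (background-subtracted, in data units), which reflects what
# the unit actually looks like even when its modal template is impure;
# without features, the modal simple template is used.
make_units <- function(spikes, templates, fs, bank = NULL) {
  ids <- sort(unique(spikes$cluster))
  nch <- if (!is.null(templates)) templates$geom$n_channels
         else bank$geom$n_channels
  lapply(ids, function(g) {
    sel <- which(spikes$cluster == g)
    tid <- as.integer(names(which.max(table(spikes$template_id[sel]))))
    W <- if (!is.null(spikes$feat)) {
      basis <- if (!is.null(templates)) templates$basis
               else default_pc_basis(bank$n_t)
      acc <- matrix(0, nch, ncol(spikes$feat[[sel[1]]]))
      cnt <- numeric(nch)
      for (i in sel) {
        ch <- spikes$chans[[i]]
        acc[ch, ] <- acc[ch, ] + spikes$feat[[i]]
        cnt[ch] <- cnt[ch] + 1
      }
      ok <- cnt > 0
      acc[ok, ] <- acc[ok, ] / cnt[ok]
      acc %*% t(basis)
    } else if (!is.null(templates)) {
      templates$waveforms[[tid]] * mean(abs(spikes$amplitude[sel]))
    } else {
      s <- as.integer(names(which.max(table(spikes$shape[sel]))))
      z <- as.integer(names(which.max(table(spikes$size[sel]))))
      outer(bank$footprints[[z]][tid, ], bank$shapes[, s]) *
        mean(abs(spikes$amplitude[sel]))
    }
    list(times = sort(spikes$time[sel] / fs), waveform = W,
         n = length(sel), template_id = tid)
  })
}

#' @export
print.spikegraph_sort <- function(x, ...) {
  cat(sprintf("<spikegraph_sort> %d spikes, %d units (%d good)\n",
              nrow(x$spikes), nrow(x$units),
              sum(x$units$group == "good")))
  invisible(x)
}

#' Tidy methods for sort results
#'
#' `tidy()` returns the per-unit table; `glance()` a one-row run summary.
#'
#' @param x A `spikegraph_sort`.
#' @param ... Unused.
#' @export
tidy.spikegraph_sort <- function(x, ...) x$units

#' @rdname tidy.spikegraph_sort
#' @export
glance.spikegraph_sort <- function(x, ...) {
  tibble::tibble(n_spikes = nrow(x$spikes), n_units = nrow(x$units),
                 n_good = sum(x$units$group == "good"),
                 n_templates = length(x$templates$waveforms),
                 drift_range_um = if (!is.null(x$drift))
                   drift_range(x$drift$trace) else NA_real_)
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")

#' Plot the estimated drift trace
#'
#' @param result A `spikegraph_sort` (or `drift_trace`).
#' @return A ggplot object.
#' @export
plot_drift <- function(result) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  tr <- if (inherits(result, "spikegraph_sort")) result$drift$trace
        else result
  df <- tidy.drift_trace(tr)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$shift_um,
                                   color = factor(.data$block))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "drift (µm)", color = "block") +
    ggplot2::theme_minimal()
}

#' Plot learned template waveforms
#'
#' @param templates A `learned_templates` (or `spikegraph_sort`).
#' @param ids Template indices (default up to 12).
#' @return A ggplot object.
#' @export
plot_templates <- function(templates, ids = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  tl <- if (inherits(templates, "spikegraph_sort")) templates$templates
        else templates
  if (is.null(ids)) ids <- seq_len(min(12, length(tl$waveforms)))
  df <- dplyr::bind_rows(lapply(ids, function(k) {
    W <- tl$waveforms[[k]]
    bc <- template_best_channel(W)
    tibble::tibble(template = k, t = seq_len(ncol(W)), v = W[bc, ])
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$v)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~template) +
    ggplot2::labs(x = "sample", y = "best-channel amplitude (norm units)") +
    ggplot2::theme_minimal()
}
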