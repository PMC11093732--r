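# Ground-truth matching and benchmark summaries.

#' Match ground-truth units to sorted units
#'
#' Every ground-truth unit is compared to the `n_candidates` detected units
#' closest by best-channel distance. Against each candidate the spikes are
#' matched greedily one-to-one, nearest in time first, within `tol_ms`;
#' FP is the fraction of the candidate's spikes without a match, FN the
#' fraction of ground-truth spikes missed, and the candidate maximizing
#' `score = 1 - FP - FN` is kept.
#'
#' @param truth_trains List of ground-truth spike-time vectors (samples).
#' @param truth_pos Ground-truth unit positions (um, vector of y or n x 2).
#' @param sorted_trains List of detected units' spike times (samples).
#' @param sorted_pos Detected unit positions (same convention).
#' @param fs Sampling rate, Hz.
#' @param tol_ms Matching tolerance (default 0.2 ms).
#' @param n_candidates Candidate pool size (default 40).
#' @return Tibble: `unit`, `matched_id`, `FP`, `FN`, `score`, `n_truth`,
#'   `n_matched_spikes`.
#' @export
match_units <- function(truth_trains, truth_pos, sorted_trains, sorted_pos,
                        fs = 30000, tol_ms = 0.2, n_candidates = 40) {
  if (!length(sorted_trains)) {
    return(tibble::tibble(unit = seq_along(truth_trains),
                          matched_id = NA_integer_, FP = NA_real_,
                          FN = NA_real_, score = NA_real_,
                          n_truth = lengths(truth_trains),
                          n_matched_spikes = NA_real_))
  }
  as_xy <- function(p) if (is.null(dim(p))) cbind(0, p) else p
  tp <- as_xy(truth_pos); sp <- as_xy(sorted_pos)
  tol <- tol_ms / 1000 * fs
  out <- lapply(seq_along(truth_trains), function(u) {
    tt <- sort(truth_trains[[u]])
    d2 <- (sp[, 1] - tp[u, 1])^2 + (sp[, 2] - tp[u, 2])^2
    cand <- order(d2, seq_along(sorted_trains))[
      seq_len(min(n_candidates, length(sorted_trains)))]
    best <- list(score = -Inf)
    for (j in cand) {
      dt <- sort(sorted_trains[[j]])
      nm <- cpp_match_count(tt, dt, tol)
      FP <- 1 - nm / max(1, length(dt))
      FN <- 1 - nm / max(1, length(tt))
      sc <- 1 - FP - FN
      if (sc > best$score)
        best <- list(score = sc, FP = FP, FN = FN, id = j, nm = nm)
    }
    tibble::tibble(unit = u, matched_id = best$id, FP = best$FP,
                   FN = best$FN, score = best$score, n_truth = length(tt),
                   n_matched_spikes = best$nm)
  })
  dplyr::bind_rows(out)
}

#' Summarize a benchmark
#'
#' Counts ground-truth units matched at `score > score_threshold`, how many
#' of the matches are labeled good, and how many good detected units match
#' no ground-truth unit (false-positive units).
#'
#' @param matches Output of [match_units()].
#' @param good_labels Character vector (`"good"`/`"mua"`) per detected
#'   unit.
#' @param score_threshold Default 0.8.
#' @return One-row tibble: `n_truth`, `n_matched`, `n_matched_good`,
#'   `n_false_positive_units`, `mean_score`.
#' @export
summarize_sorting <- function(matches, good_labels,
                              score_threshold = 0.8) {
  hit <- !is.na(matches$score) & matches$score > score_threshold
  matched_ids <- unique(matches$matched_id[hit])
  good_ids <- which(good_labels == "good")
  tibble::tibble(
    n_truth = nrow(matches),
    n_matched = sum(hit),
    n_matched_good = sum(matches$matched_id[hit] %in% good_ids),
    n_false_positive_units = length(setdiff(good_ids, matched_ids)),
    mean_score = mean(matches$score, na.rm = TRUE))
}

#' Drift range of a trace
#'
#' The difference between the 95th and 5th percentile (linear
#' interpolation) of the median drift across positions.
#'
#' @param trace A `drift_trace`, `drift_profile`, or bare time x positions
#'   matrix (um).
#' @return Range in micrometers.
#' @export
drift_range <- function(trace) {
  v <- if (inherits(trace, "drift_trace")) trace$values
       else if (inherits(trace, "drift_profile")) trace$trace
       else trace
  med <- apply(as.matrix(v), 1, stats::median)
  unname(diff(stats::quantile(med, c(0.05, 0.95), type = 7)))
}
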