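#' Handle to a flat binary recording
#'
#' The on-disk layout is sample-major ("row = time sample, column = channel",
#' C order): all channels for sample 0, then all channels for sample 1, and
#' so on. Integer samples are converted to float at load time and are not
#' rescaled (a `gain` option is available in the run configuration).
#'
#' @param path Path to the binary file.
#' @param n_channels_total Number of columns stored in the file.
#' @param sampling_rate Sampling rate in Hz.
#' @param dtype One of `"int16"`, `"uint16"`, `"int32"`, `"float32"`.
#' @param n_samples Number of samples; inferred from the file size when
#'   `NULL`. An error is raised if the file size is not a whole number of
#'   samples.
#' @return An object of class `recording_handle`.
#' @export
recording_handle <- function(path, n_channels_total, sampling_rate,
                             dtype = "int16", n_samples = NULL) {
  dtype <- match.arg(dtype, c("int16", "uint16", "int32", "float32"))
  stopifnot(sampling_rate > 0, n_channels_total >= 1)
  bytes <- switch(dtype, int16 = 2L, uint16 = 2L, int32 = 4L, float32 = 4L)
  sz <- file.size(path)
  if (is.na(sz)) stop("file not found: ", path)
  frame <- bytes * n_channels_total
  if (is.null(n_samples)) {
    if (sz %% frame != 0)
      stop(sprintf("file truncated mid-sample: %d bytes is not a multiple of the %d-byte frame (offset of last full frame: %d)",
                   sz, frame, (sz %/% frame) * frame))
    n_samples <- sz %/% frame
  } else if (sz < n_samples * frame) {
    stop(sprintf("file shorter than declared: have %d bytes, need %d",
                 sz, n_samples * frame))
  }
  structure(list(path = path, dtype = dtype, bytes = bytes,
                 n_channels_total = as.integer(n_channels_total),
                 sampling_rate = sampling_rate,
                 n_samples = as.numeric(n_samples)),
            class = "recording_handle")
}

#' @export
print.recording_handle <- function(x, ...) {
  cat(sprintf("<recording_handle> %s, %d ch x %.0f samples @ %g Hz (%s)\n",
              basename(x$path), x$n_channels_total, x$n_samples,
              x$sampling_rate, x$dtype))
  invisible(x)
}

#' Number of processing batches in a recording
#' @param rec A [recording_handle()].
#' @param N_T Batch size in samples.
#' @export
n_batches <- function(rec, N_T = 60000) as.integer(ceiling(rec$n_samples / N_T))

read_samples <- function(rec, from, n) {
  # from: 0-based sample index; returns n_channels_total x n matrix (float)
  con <- file(rec$path, "rb")
  on.exit(close(con))
  seek(con, from * rec$bytes * rec$n_channels_total)
  what <- if (rec$dtype == "float32") "numeric" else "integer"
  signed <- rec$dtype != "uint16"
  raw <- readBin(con, what, n = n * rec$n_channels_total, size = rec$bytes,
                 signed = if (rec$bytes == 2) signed else TRUE)
  if (length(raw) < n * rec$n_channels_total)
    stop(sprintf("file truncated mid-sample at byte offset %d",
                 from * rec$bytes * rec$n_channels_total + length(raw) * rec$bytes))
  if (rec$dtype == "uint16") raw[raw < 0] <- raw[raw < 0] + 65536
  matrix(as.numeric(raw), nrow = rec$n_channels_total)
}

#' Load one padded batch of a recording
#'
#' Returns the channel-mapped float samples for batch `batch_index`
#' (0-based), with `n_t` samples of padding on each side. The first batch's
#' left pad repeats the first sample; a short final batch is padded to the
#' full `N_T` with the repeated last value, as is its right pad. Interior
#' pads are true neighboring data.
#'
#' @param rec A [recording_handle()].
#' @param geom A [probe_geometry()].
#' @param batch_index 0-based batch index.
#' @param N_T Batch size in samples (default 60,000).
#' @param n_t Pad width in samples (default 61).
#' @return A `padded_batch`: list with `data` (channels x (N_T + 2 n_t)),
#'   `batch_index`, `N_T`, `n_t`, `t0` (0-based sample index of the first
#'   payload sample).
#' @export
load_batch <- function(rec, geom, batch_index, N_T = 60000, n_t = 61) {
  nb <- n_batches(rec, N_T)
  if (batch_index < 0 || batch_index >= nb)
    stop("batch_index out of range [0, ", nb - 1, "]")
  t0 <- batch_index * N_T
  lo <- max(0, t0 - n_t)
  hi <- min(rec$n_samples, t0 + N_T + n_t)
  raw <- read_samples(rec, lo, hi - lo)
  raw <- raw[geom$channel_map + 1L, , drop = FALSE]
  nch <- nrow(raw)
  out <- matrix(0, nch, N_T + 2 * n_t)
  # columns of `out` correspond to samples (t0 - n_t) .. (t0 + N_T + n_t - 1)
  src_cols <- (lo - (t0 - n_t) + 1):(lo - (t0 - n_t) + ncol(raw))
  out[, src_cols] <- raw
  if (t0 - n_t < 0)               # first batch: repeat first sample
    out[, seq_len(src_cols[1] - 1)] <- raw[, 1]
  if (hi < t0 + N_T + n_t)        # short final batch: repeat last value
    out[, (src_cols[length(src_cols)] + 1):(N_T + 2 * n_t)] <- raw[, ncol(raw)]
  structure(list(data = out, batch_index = as.integer(batch_index),
                 N_T = as.integer(N_T), n_t = as.integer(n_t), t0 = t0),
            class = "padded_batch")
}

#' Payload (unpadded) portion of a padded batch
#' @param batch A `padded_batch`.
#' @export
batch_payload <- function(batch) {
  batch$data[, (batch$n_t + 1):(batch$n_t + batch$N_T), drop = FALSE]
}

#' Write a matrix as a flat binary recording
#'
#' @param data channels x samples matrix (channel c goes to file column
#'   `channel_map[c]`).
#' @param path Output path.
#' @param dtype Storage type.
#' @param channel_map 0-based file column per row of `data`.
#' @export
write_recording_bin <- function(data, path, dtype = "int16",
                                channel_map = NULL) {
  dtype <- match.arg(dtype, c("int16", "uint16", "int32", "float32"))
  n <- nrow(data)
  if (is.null(channel_map)) channel_map <- 0:(n - 1)
  full <- matrix(0, n, ncol(data))
  full[channel_map + 1L, ] <- data
  con <- file(path, "wb")
  on.exit(close(con))
  v <- as.vector(full) # column-major = sample-major frames
  if (dtype == "float32") {
    writeBin(v, con, size = 4)
  } else {
    size <- if (dtype == "int32") 4L else 2L
    writeBin(as.integer(round(v)), con, size = size)
  }
  invisible(path)
}
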