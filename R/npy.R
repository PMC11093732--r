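# Minimal reader/writer for the ".npy" array format (version 1.0, C order),
# covering the dtypes Phy consumes: int32, int64, float32, float64.
# No R package on our dependency stack emits this format, so it is
# implemented here; the subset is round-trip tested.

npy_descr <- function(dtype) {
  switch(dtype,
         int32 = "<i4", int64 = "<i8",
         float32 = "<f4", float64 = "<f8",
         stop("unsupported dtype: ", dtype))
}

#' Write an array in npy format
#'
#' @param x Vector or matrix (matrices are written C-order, rows first).
#' @param path Output path.
#' @param dtype One of `"int32"`, `"int64"`, `"float32"`, `"float64"`.
#' @export
write_npy <- function(x, path, dtype = "float64") {
  if (any(!is.finite(x)) && length(x))
    stop("non-finite values cannot be written to ", basename(path))
  shape <- if (is.matrix(x)) dim(x) else length(x)
  shape_s <- if (length(shape) == 1) sprintf("(%d,)", shape)
             else paste0("(", paste(shape, collapse = ", "), ")")
  header <- sprintf("{'descr': '%s', 'fortran_order': False, 'shape': %s, }",
                    npy_descr(dtype), shape_s)
  # pad header so that total preamble length is a multiple of 64
  pre <- 10L
  pad <- 64L - ((pre + nchar(header) + 1L) %% 64L)
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("\x93NUMPY"), con)
  writeBin(as.raw(c(1L, 0L)), con)
  writeBin(as.integer(nchar(header)), con, size = 2, endian = "little")
  writeChar(header, con, eos = NULL)
  v <- if (is.matrix(x)) as.vector(t(x)) else as.vector(x) # C order
  switch(dtype,
    int32 = writeBin(as.integer(v), con, size = 4, endian = "little"),
    int64 = { # emulate 64-bit ints: split into low/high 32-bit words
      v <- as.numeric(v)
      lo <- as.integer(v %% 2^32 - ifelse(v %% 2^32 >= 2^31, 2^32, 0))
      hi <- as.integer(floor(v / 2^32))
      m <- rbind(lo, hi)
      writeBin(as.integer(m), con, size = 4, endian = "little")
    },
    float32 = writeBin(as.numeric(v), con, size = 4, endian = "little"),
    float64 = writeBin(as.numeric(v), con, size = 8, endian = "little"))
  invisible(path)
}

#' Read an npy array written by [write_npy()]
#' @param path File path.
#' @return A vector or matrix.
#' @export
read_npy <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6)
  if (!identical(rawToChar(magic[2:6]), "NUMPY")) stop("not an npy file")
  readBin(con, "raw", 2) # version
  hlen <- readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE)
  header <- rawToChar(readBin(con, "raw", hlen))
  descr <- sub(".*'descr': '([^']+)'.*", "\\1", header)
  shape_s <- sub(".*'shape': \\(([0-9, ]*)\\).*", "\\1", header)
  shape <- as.integer(strsplit(gsub(" ", "", shape_s), ",")[[1]])
  n <- prod(shape)
  v <- switch(descr,
    "<i4" = readBin(con, "integer", n, size = 4, endian = "little"),
    "<i8" = if (n == 0) numeric(0) else {
              w <- readBin(con, "integer", 2 * n, size = 4, endian = "little")
              lo <- w[seq(1, 2 * n, 2)]; hi <- w[seq(2, 2 * n, 2)]
              (lo + ifelse(lo < 0, 2^32, 0)) + 2^32 * hi },
    "<f4" = readBin(con, "numeric", n, size = 4, endian = "little"),
    "<f8" = readBin(con, "numeric", n, size = 8, endian = "little"),
    stop("unsupported descr: ", descr))
  if (length(shape) == 2) matrix(v, shape[1], shape[2], byrow = TRUE) else v
}

#' Write Phy-compatible sorting output
#'
#' Emits the minimal array-file set Phy needs: `spike_times.npy` (samples,
#' int64), `spike_clusters.npy` (int32), `amplitudes.npy`, `templates.npy`
#' (units x time x channels, float32), `channel_positions.npy`, plus
#' `cluster_group.tsv` with group labels (`good` / `mua`).
#'
#' @param spikes Spike table (tibble) with columns `time` (integer samples),
#'   `cluster`, `amplitude`; must be sorted by time.
#' @param templates List with `waveforms` (list of channels x n_t matrices,
#'   one per cluster id in sorted order) or `NULL`.
#' @param geom A [probe_geometry()].
#' @param out_dir Output directory (created if missing).
#' @param groups Optional named character vector of cluster group labels.
#' @return Invisibly, a manifest tibble of the files written.
#' @export
write_phy_output <- function(spikes, templates, geom, out_dir,
                             groups = NULL) {
  if (nrow(spikes) && is.unsorted(spikes$time))
    stop("spikes must be sorted by time")
  bad <- vapply(c("time", "cluster", "amplitude"),
                function(f) any(!is.finite(spikes[[f]])), logical(1))
  if (any(bad)) stop("non-finite spike fields: ",
                     paste(names(bad)[bad], collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(out_dir, f)
  write_npy(spikes$time, fp("spike_times.npy"), "int64")
  write_npy(as.integer(spikes$cluster), fp("spike_clusters.npy"), "int32")
  write_npy(spikes$amplitude, fp("amplitudes.npy"), "float64")
  if (!is.null(templates) && length(templates$waveforms)) {
    tl <- templates$waveforms
    arr <- matrix(0, length(tl), length(tl[[1]]))
    for (i in seq_along(tl)) arr[i, ] <- as.vector(t(tl[[i]])) # time-major
    write_npy(arr, fp("templates.npy"), "float64")
  }
  write_npy(cbind(geom$x, geom$y), fp("channel_positions.npy"), "float64")
  ids <- sort(unique(as.integer(spikes$cluster)))
  grp <- if (is.null(groups)) setNames(rep("mua", length(ids)), ids) else groups
  write.table(data.frame(cluster_id = names(grp), group = unname(grp)),
              fp("cluster_group.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  files <- c("spike_times.npy", "spike_clusters.npy", "amplitudes.npy",
             "channel_positions.npy", "cluster_group.tsv")
  if (!is.null(templates) && length(templates$waveforms))
    files <- c(files, "templates.npy")
  invisible(tibble::tibble(file = files,
                           path = vapply(files, fp, character(1))))
}
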