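#' Probe geometry
#'
#' A probe geometry holds the physical channel layout used throughout the
#' pipeline: per-channel x/y coordinates in micrometers and the channel map,
#' i.e. which column of the binary file each recorded channel lives in.
#'
#' @param x,y Numeric vectors of channel coordinates in micrometers.
#' @param channel_map Integer vector (0-based) giving, for each channel, its
#'   column index in the binary file. Defaults to `0:(n-1)`.
#' @return An object of class `probe_geometry` with fields `x`, `y`,
#'   `channel_map` and `n_channels`.
#' @export
probe_geometry <- function(x, y, channel_map = NULL) {
  stopifnot(length(x) == length(y), length(x) >= 1,
            all(is.finite(x)), all(is.finite(y)))
  n <- length(x)
  if (is.null(channel_map)) channel_map <- 0:(n - 1)
  channel_map <- as.integer(channel_map)
  stopifnot(length(channel_map) == n, !anyDuplicated(channel_map),
            all(channel_map >= 0))
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 channel_map = channel_map, n_channels = n),
            class = "probe_geometry")
}

#' @export
print.probe_geometry <- function(x, ...) {
  cat(sprintf("<probe_geometry> %d channels, x span %.0f um, y span %.0f um\n",
              x$n_channels, diff(range(x$x)), diff(range(x$y))))
  invisible(x)
}

#' Neuropixels 1.0 probe layout
#'
#' 384 sites in a checkerboard: 20 um vertical spacing between rows, 32 um
#' horizontal spacing within a row, and a 16 um horizontal offset between
#' alternating rows.
#'
#' @return A [probe_geometry()].
#' @export
probe_np1 <- function() {
  n <- 384L
  row <- (0:(n - 1)) %/% 2L
  colr <- (0:(n - 1)) %% 2L
  x <- ifelse(row %% 2L == 0L, c(16, 48)[colr + 1L], c(0, 32)[colr + 1L])
  y <- 20 * (row + 1)
  probe_geometry(x, y)
}

#' Single- or multi-column test probe
#'
#' @param n_channels Number of channels.
#' @param n_cols Number of columns.
#' @param pitch Vertical spacing between rows, micrometers.
#' @param col_spacing Horizontal spacing between columns, micrometers.
#' @return A [probe_geometry()].
#' @export
probe_linear <- function(n_channels, n_cols = 1, pitch = 20,
                         col_spacing = 32) {
  idx <- 0:(n_channels - 1)
  probe_geometry(x = (idx %% n_cols) * col_spacing,
                 y = (idx %/% n_cols) * pitch)
}

#' Read / write a probe file
#'
#' Probe files are JSON (or YAML) with fields `x`, `y`, `channel_map`.
#'
#' @param path File path.
#' @return A [probe_geometry()].
#' @export
read_probe <- function(path) {
  p <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
       else jsonlite::read_json(path, simplifyVector = TRUE)
  probe_geometry(p$x, p$y, p$channel_map)
}

#' @rdname read_probe
#' @param geom A [probe_geometry()].
#' @export
write_probe <- function(geom, path) {
  jsonlite::write_json(list(x = geom$x, y = geom$y,
                            channel_map = geom$channel_map),
                       path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

# Grid of candidate template positions at twice the channel density in each
# dimension: every channel contributes its own site plus offsets of half the
# inter-row/inter-column pitch. For a 384-site Neuropixels 1.0 probe this
# yields 1,536 positions.
template_positions <- function(geom) {
  ux <- sort(unique(geom$x)); uy <- sort(unique(geom$y))
  dy <- if (length(uy) > 1) stats::median(diff(uy)) else 20
  dx <- if (length(ux) > 1) stats::median(diff(ux)) else dy
  px <- c(geom$x, geom$x + dx / 2, geom$x, geom$x + dx / 2)
  py <- c(geom$y, geom$y, geom$y + dy / 2, geom$y + dy / 2)
  pos <- unique(cbind(x = px, y = py))
  pos[order(pos[, "y"], pos[, "x"]), , drop = FALSE]
}
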