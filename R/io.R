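# Format readers/writers: multi-page TIFF stacks (with a JSON sidecar
# recording the intensity scale), track tables, polyline annotations.

#' Write an image stack as multi-page TIFF
#'
#' Frames are stored as 16-bit pages scaled by a single factor recorded in
#' a `<path>.json` sidecar, so that [read_stack_tiff()] restores the
#' original intensities. Axis order is T(Y)(X), one page per frame.
#'
#' @param stack numeric array `T x Y x X`, or a matrix for a single frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  if (is.matrix(stack)) stack <- array(stack, c(1L, dim(stack)))
  scale <- max(stack, 1e-12)
  pages <- lapply(seq_len(dim(stack)[1L]), function(i) stack[i, , ] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(list(scale = scale, n_frames = dim(stack)[1L],
                            axes = "TYX"),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read an image stack written by [write_stack_tiff()]
#'
#' Plain TIFF stacks from other sources are read too (without a sidecar
#' the 0..1-normalised values are returned as stored).
#'
#' @param path TIFF file.
#' @return numeric array `T x Y x X`.
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  scale <- 1
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    scale <- jsonlite::read_json(sidecar)$scale
  }
  out <- array(0, c(length(pages), nrow(pages[[1L]]), ncol(pages[[1L]])))
  for (i in seq_along(pages)) out[i, , ] <- pages[[i]] * scale
  out
}

#' Write trajectories to the canonical track CSV dialect
#'
#' Columns `cell_id`, `t`, `x`, `y` (seconds and micrometres), one row per
#' frame, readable by [load_tracks()] with default column mapping.
#'
#' @param trajectories list of [trajectory()] objects.
#' @param path output CSV.
#' @export
write_tracks_csv <- function(trajectories, path) {
  rows <- do.call(rbind, lapply(trajectories, function(tr) {
    data.frame(cell_id = attr(tr, "cell_id"), t = tr$t, x = tr$x, y = tr$y,
               stringsAsFactors = FALSE)
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read or write a polyline annotation as JSON
#'
#' @param path JSON file holding `{"x": [...], "y": [...]}` in pixel
#'   coordinates.
#' @return matrix with columns `x`, `y`.
#' @export
read_polyline_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cbind(x = as.numeric(obj$x), y = as.numeric(obj$y))
}

#' @rdname read_polyline_json
#' @param path output file.
#' @param polyline matrix with columns `x`, `y`.
#' @export
write_polyline_json <- function(polyline, path) {
  jsonlite::write_json(list(x = polyline[, "x"], y = polyline[, "y"]),
                       path, digits = NA)
  invisible(path)
}
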