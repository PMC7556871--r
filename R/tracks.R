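#' Build a trajectory object
#'
#' A trajectory is a time-ordered sequence of cell positions in micrometres.
#' Internally it is a plain `data.frame` with columns `t` (seconds, strictly
#' increasing), `x`, `y` (um) and optionally `z`, carrying the cell id and
#' data source as attributes.
#'
#' @param t numeric vector of time stamps in seconds, strictly increasing.
#' @param x,y numeric coordinates in micrometres.
#' @param z optional numeric z coordinate in micrometres. Ignored by the 2D
#'   kinematics unless `use_z = TRUE` is passed to those functions.
#' @param cell_id identifier for the cell (scalar, coerced to character).
#' @param source free-text provenance tag.
#' @return a `data.frame` of class `"trajectory"`.
#' @examples
#' tr <- trajectory(t = c(0, 15, 30), x = c(0, 0.5, 1), y = c(0, 0, 0))
#' net_displacement(tr)
#' @export
trajectory <- function(t, x, y, z = NULL, cell_id = "cell", source = "") {
  if (length(t) < 2L) {
    stop("a trajectory needs at least 2 points", call. = FALSE)
  }
  if (length(x) != length(t) || length(y) != length(t)) {
    stop("`t`, `x`, `y` must have equal length", call. = FALSE)
  }
  if (!all(is.finite(t)) || !all(is.finite(x)) || !all(is.finite(y))) {
    stop("trajectory coordinates and times must be finite", call. = FALSE)
  }
  if (any(diff(t) <= 0)) {
    stop(sprintf("time stamps must be strictly increasing (cell '%s')",
                 cell_id), call. = FALSE)
  }
  out <- data.frame(t = as.numeric(t), x = as.numeric(x), y = as.numeric(y))
  if (!is.null(z)) {
    if (length(z) != length(t)) stop("`z` length mismatch", call. = FALSE)
    out$z <- as.numeric(z)
  }
  attr(out, "cell_id") <- as.character(cell_id)[1L]
  attr(out, "source") <- source
  class(out) <- c("trajectory", "data.frame")
  out
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> cell '%s': %d points, %.0f s, net %.2f um\n",
              attr(x, "cell_id"), nrow(x), x$t[nrow(x)] - x$t[1L],
              net_displacement(x)))
  invisible(x)
}

#' Load trajectories from a tracking table
#'
#' Reads a CSV export from a tracking tool (Imaris, TrackMate, custom) and
#' returns one [trajectory()] per cell. Arbitrary column headers are mapped
#' through `columns`; pixel coordinates are converted to micrometres via
#' `pixel_size`.
#'
#' @param path CSV file with one row per (cell, frame).
#' @param columns named character vector mapping the canonical names
#'   `cell_id`, `t`, `x`, `y` (optionally `z`) to the file's headers.
#' @param pixel_size um per pixel applied to `x`, `y` (and `z`); use the
#'   default `1` when coordinates are already in micrometres.
#' @param time_scale multiplier taking the file's time unit to seconds
#'   (e.g. `60` for minutes).
#' @return named list of trajectories, sorted by time within each cell.
#' @export
load_tracks <- function(path,
                        columns = c(cell_id = "cell_id", t = "t",
                                    x = "x", y = "y"),
                        pixel_size = 1, time_scale = 1) {
  if (!file.exists(path)) {
    stop(sprintf("track file not found: %s", path), call. = FALSE)
  }
  stopifnot_scalar(pixel_size, "pixel_size", positive = TRUE)
  stopifnot_scalar(time_scale, "time_scale", positive = TRUE)
  tab <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("cell_id", "t", "x", "y")
  if (!all(need %in% names(columns))) {
    stop("`columns` must map cell_id, t, x, y", call. = FALSE)
  }
  missing_cols <- setdiff(unname(columns), names(tab))
  if (length(missing_cols)) {
    stop(sprintf("columns not found in %s: %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  ids <- as.character(tab[[columns[["cell_id"]]]])
  out <- lapply(split(seq_len(nrow(tab)), ids), function(idx) {
    sub <- tab[idx, , drop = FALSE]
    tt <- as.numeric(sub[[columns[["t"]]]]) * time_scale
    ord <- order(tt)
    tt <- tt[ord]
    cell <- ids[idx[1L]]
    if (anyDuplicated(tt)) {
      stop(sprintf("duplicate time stamps for cell '%s' in %s", cell, path),
           call. = FALSE)
    }
    zz <- if ("z" %in% names(columns)) {
      as.numeric(sub[[columns[["z"]]]])[ord] * pixel_size
    }
    tr <- trajectory(
      t = tt,
      x = as.numeric(sub[[columns[["x"]]]])[ord] * pixel_size,
      y = as.numeric(sub[[columns[["y"]]]])[ord] * pixel_size,
      z = zz, cell_id = cell, source = path
    )
    dt <- diff(tt)
    if (any(dt > 2 * median(dt))) {
      warning(sprintf("cell '%s': gaps > 2x median frame interval", cell),
              call. = FALSE)
    }
    tr
  })
  out[order(names(out))]
}

step_vectors <- function(traj, use_z = FALSE) {
  n <- nrow(traj)
  d <- cbind(diff(traj$x), diff(traj$y))
  if (use_z && !is.null(traj$z)) d <- cbind(d, diff(traj$z))
  d
}

#' Instantaneous speed trace
#'
#' Speed between consecutive time points: `v_i = |p_{i+1} - p_i| / dt_i`,
#' reported in um/h against the midpoint time of each frame pair.
#' Non-uniform frame intervals are handled per pair.
#'
#' @param traj a [trajectory()].
#' @param use_z include the z coordinate in distances (default `FALSE`;
#'   tracking of this kind is typically done on per-wavelength maximum
#'   projections, so 2D distances are the default).
#' @return a `data.frame` of class `"speed_trace"` with columns `t_mid`
#'   (s), `v` (um/h) and attribute `cell_id`; one row per frame pair, and
#'   attribute `frame_t` holding the original frame times (needed to map
#'   speeds back onto frame intervals).
#' @export
instantaneous_speed <- function(traj, use_z = FALSE) {
  stopifnot(inherits(traj, "trajectory"))
  d <- step_vectors(traj, use_z)
  dt <- diff(traj$t)
  v_um_s <- sqrt(rowSums(d^2)) / dt
  out <- data.frame(t_mid = traj$t[-nrow(traj)] + dt / 2,
                    v = v_um_s * 3600)
  attr(out, "cell_id") <- attr(traj, "cell_id")
  attr(out, "frame_t") <- traj$t
  class(out) <- c("speed_trace", "data.frame")
  out
}

#' Net displacement of a trajectory
#'
#' Euclidean norm of the vector between the first and last recorded
#' positions — the "distance of migration" of a time-lapse experiment.
#' Always bounded above by [path_length()].
#'
#' @inheritParams instantaneous_speed
#' @return displacement in um.
#' @export
net_displacement <- function(traj, use_z = FALSE) {
  stopifnot(inherits(traj, "trajectory"))
  n <- nrow(traj)
  d2 <- (traj$x[n] - traj$x[1L])^2 + (traj$y[n] - traj$y[1L])^2
  if (use_z && !is.null(traj$z)) d2 <- d2 + (traj$z[n] - traj$z[1L])^2
  sqrt(d2)
}

#' Total path length of a trajectory
#'
#' Sum of consecutive step lengths in um.
#'
#' @inheritParams instantaneous_speed
#' @export
path_length <- function(traj, use_z = FALSE) {
  stopifnot(inherits(traj, "trajectory"))
  sum(sqrt(rowSums(step_vectors(traj, use_z)^2)))
}
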