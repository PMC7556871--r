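#' Default phase-segmentation thresholds
#'
#' Migratory speeds in this system cluster near 110-116 um/h while
#' stationary speeds sit near zero, so the hysteresis thresholds are placed
#' in the anti-mode between the two: a cell enters the migratory state when
#' its smoothed speed reaches `v_on` and leaves it when the speed falls
#' below `v_off` (`v_off < v_on` prevents chatter near a single threshold).
#'
#' @param v_on entry threshold, um/h.
#' @param v_off exit threshold, um/h; must be `< v_on`.
#' @param smooth_window moving-average window in frames (centred).
#' @param min_dwell_frames phases shorter than this many frame intervals
#'   are merged into a neighbour.
#' @return list of class `"phase_config"`.
#' @export
phase_config <- function(v_on = 40, v_off = 20, smooth_window = 3L,
                         min_dwell_frames = 2L) {
  stopifnot_scalar(v_on, "v_on", positive = TRUE)
  stopifnot_scalar(v_off, "v_off", nonneg = TRUE)
  if (v_off >= v_on) stop("`v_off` must be < `v_on`", call. = FALSE)
  structure(list(v_on = v_on, v_off = v_off,
                 smooth_window = as.integer(smooth_window),
                 min_dwell_frames = as.integer(min_dwell_frames)),
            class = "phase_config")
}

# centred moving average with shrinking window at the edges
moving_average <- function(v, w) {
  if (w <= 1L) return(v)
  half <- (w - 1L) %/% 2L
  n <- length(v)
  vapply(seq_len(n), function(i) {
    mean(v[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
}

# merge runs shorter than min_dwell into a neighbour; the neighbour with
# the longer run wins, ties go to the earlier neighbour
merge_short_runs <- function(states, min_dwell) {
  repeat {
    r <- rle(states)
    if (length(r$lengths) <= 1L) return(states)
    short <- which(r$lengths < min_dwell)
    if (!length(short)) return(states)
    i <- short[which.min(r$lengths[short])]  # shortest first, earliest tie
    left <- if (i > 1L) r$lengths[i - 1L] else -1L
    right <- if (i < length(r$lengths)) r$lengths[i + 1L] else -1L
    take <- if (left >= right) r$values[i - 1L] else r$values[i + 1L]
    ends <- cumsum(r$lengths)
    starts <- c(1L, head(ends, -1L) + 1L)
    states[starts[i]:ends[i]] <- take
  }
}

#' Segment a speed trace into migratory and stationary phases
#'
#' Formalises the manual phase-calling convention: the instantaneous speed
#' is smoothed with a short moving average, classified by hysteresis
#' (enter migratory at `v_on`, exit below `v_off`), and phases shorter
#' than `min_dwell_frames` are merged into their dominant neighbour.
#' Phase boundaries fall on frame times; the phases tile the movie.
#'
#' @param trace a speed trace from [instantaneous_speed()].
#' @param cfg a [phase_config()].
#' @return object of class `"phase_segmentation"`: a data.frame with
#'   columns `state` (`"MIG"`/`"STAT"`), `t_start`, `t_end` (s), plus
#'   attributes `cell_id`, `config` and `interval_states` (the per-frame-
#'   interval classification the phases were built from).
#' @export
segment_phases <- function(trace, cfg = phase_config()) {
  stopifnot(inherits(trace, "speed_trace"), inherits(cfg, "phase_config"))
  if (nrow(trace) < 2L) stop("speed trace too short", call. = FALSE)
  frame_t <- attr(trace, "frame_t")
  if (is.null(frame_t)) {
    # reconstruct frame times from midpoints assuming contiguous intervals
    dt <- diff(trace$t_mid)
    frame_t <- c(trace$t_mid[1L] - dt[1L] / 2,
                 trace$t_mid + c(dt / 2, dt[length(dt)] / 2))
  }
  vs <- moving_average(trace$v, cfg$smooth_window)
  n <- length(vs)
  st <- character(n)
  cur <- if (vs[1L] >= cfg$v_on) "MIG" else "STAT"
  for (i in seq_len(n)) {
    if (cur == "STAT" && vs[i] >= cfg$v_on) cur <- "MIG"
    else if (cur == "MIG" && vs[i] < cfg$v_off) cur <- "STAT"
    st[i] <- cur
  }
  st <- merge_short_runs(st, cfg$min_dwell_frames)
  # Smoothing smears each transition across the window, which would
  # systematically dilate migratory phases; snap intervals within the
  # half-window of every state change back to their raw-speed class
  # (threshold at the hysteresis midpoint), then re-merge.
  half <- (cfg$smooth_window - 1L) %/% 2L
  if (half > 0L) {
    v_mid <- (cfg$v_on + cfg$v_off) / 2
    raw <- ifelse(trace$v >= v_mid, "MIG", "STAT")
    if (length(unique(st)) > 1L) {
      changes <- which(st[-1L] != st[-n])
      near <- unique(unlist(lapply(changes, function(b) {
        max(1L, b - half + 1L):min(n, b + half)
      })))
      st[near] <- raw[near]
      st <- merge_short_runs(st, cfg$min_dwell_frames)
    }
    # recover pauses/bursts the smoothing erased: sustained runs (at least
    # min_dwell frames) whose raw-speed class disagrees with the assigned
    # phase become phases of their own
    dis <- rle(st != raw)
    ends <- cumsum(dis$lengths)
    starts <- c(1L, head(ends, -1L) + 1L)
    for (q in which(dis$values & dis$lengths >= cfg$min_dwell_frames)) {
      st[starts[q]:ends[q]] <- raw[starts[q]:ends[q]]
    }
    st <- merge_short_runs(st, cfg$min_dwell_frames)
  }
  seg <- states_to_phases(st, frame_t)
  attr(seg, "cell_id") <- attr(trace, "cell_id")
  attr(seg, "config") <- cfg
  attr(seg, "interval_states") <- st
  class(seg) <- c("phase_segmentation", "data.frame")
  seg
}

#' @export
print.phase_segmentation <- function(x, ...) {
  cat(sprintf("<phase_segmentation> cell '%s': %d phases (%d migratory)\n",
              attr(x, "cell_id"), nrow(x), sum(x$state == "MIG")))
  print(as.data.frame(x))
  invisible(x)
}

#' Migration metrics for one cell
#'
#' The three readouts used to characterise saltatory migration over a
#' movie: the distance of migration (net displacement between the first
#' and last positions), the percentage of the movie spent in migratory
#' phases, and the mean instantaneous speed during migratory phases only.
#'
#' @param traj the cell's [trajectory()].
#' @param seg its [segment_phases()] result (same cell).
#' @return one-row data.frame: `cell_id`, `distance_um`,
#'   `percent_migratory`, `speed_migratory_um_h` (`NA` when the cell has no
#'   migratory phase), `n_phases_mig`.
#' @export
migration_metrics <- function(traj, seg) {
  stopifnot(inherits(traj, "trajectory"), inherits(seg, "phase_segmentation"))
  id_t <- attr(traj, "cell_id"); id_s <- attr(seg, "cell_id")
  if (!is.null(id_s) && !identical(id_t, id_s)) {
    stop(sprintf("trajectory ('%s') and segmentation ('%s') cell ids differ",
                 id_t, id_s), call. = FALSE)
  }
  movie_dur <- traj$t[nrow(traj)] - traj$t[1L]
  mig <- seg$state == "MIG"
  mig_dur <- sum(seg$t_end[mig] - seg$t_start[mig])
  sp <- instantaneous_speed(traj)
  st <- attr(seg, "interval_states")
  speed_mig <- if (any(mig)) {
    if (is.null(st)) {
      # fall back to locating intervals inside migratory phases by midpoint
      in_mig <- vapply(sp$t_mid, function(tm) {
        any(tm >= seg$t_start[mig] & tm <= seg$t_end[mig])
      }, logical(1))
      mean(sp$v[in_mig])
    } else {
      mean(sp$v[st == "MIG"])
    }
  } else {
    NA_real_
  }
  data.frame(cell_id = id_t,
             distance_um = net_displacement(traj),
             percent_migratory = 100 * mig_dur / movie_dur,
             speed_migratory_um_h = speed_mig,
             n_phases_mig = sum(mig),
             stringsAsFactors = FALSE)
}

#' Drop cells that never migrated
#'
#' Cells that remain stationary for the entire movie are excluded from
#' migration statistics (their migratory speed is undefined and their
#' inclusion would conflate "never moved" with "moved little").
#'
#' @param metrics data.frame of per-cell rows from [migration_metrics()].
#' @return the filtered data.frame; the number of removed cells is
#'   reported via `message()` and stored in attribute `n_removed`.
#' @export
filter_fully_stationary <- function(metrics) {
  keep <- metrics$n_phases_mig > 0
  removed <- sum(!keep)
  if (removed > 0) {
    message(sprintf("excluded %d fully stationary cell(s)", removed))
  }
  out <- metrics[keep, , drop = FALSE]
  attr(out, "n_removed") <- removed
  out
}
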