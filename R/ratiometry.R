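#' Compute a biosensor ratio trace from two single-wavelength stacks
#'
#' For each frame the two excitation channels are max-projected over z (if
#' a z dimension is present), the mean intensity inside the cell mask is
#' extracted per channel, and the ratio of channel means (not the mean of
#' pixel ratios) is formed. For PercevalHR the conventional orientation is
#' numerator = 482 nm excitation, denominator = 430 nm, so a higher ATP/ADP
#' ratio gives a higher `r`; the orientation is configurable via which
#' stack is passed as numerator.
#'
#' Frames whose denominator mean falls below `den_floor` are flagged
#' invalid (`valid = FALSE`, `r = NA`) rather than dropped, so the time
#' base stays intact. By default the floor is estimated per frame from the
#' mask complement as background mean + 3 background SD.
#'
#' @param stack_num,stack_den numeric arrays, `T x Y x X` or
#'   `T x Z x Y x X`, co-registered and equal in shape.
#' @param mask logical `Y x X` matrix (or `T x Y x X` array for a moving
#'   mask) selecting the cell.
#' @param t frame times in seconds; defaults to
#'   `(0:(T-1)) * frame_interval`.
#' @param frame_interval seconds, used only when `t` is `NULL`.
#' @param den_floor minimum admissible denominator mean; `NULL` for the
#'   per-frame background estimate.
#' @param cell_id identifier carried through to downstream results.
#' @param channel_pair numeric length-2 vector, excitation wavelengths (nm)
#'   of numerator and denominator (metadata).
#' @return data.frame of class `"ratio_trace"` with columns `t`, `r`,
#'   `num_mean`, `den_mean`, `valid`.
#' @export
compute_ratio_trace <- function(stack_num, stack_den, mask, t = NULL,
                                frame_interval = 30, den_floor = NULL,
                                cell_id = "cell",
                                channel_pair = c(482, 430)) {
  if (!identical(dim(stack_num), dim(stack_den))) {
    stop("numerator and denominator stacks differ in shape", call. = FALSE)
  }
  nd <- length(dim(stack_num))
  if (!nd %in% c(3L, 4L)) {
    stop("stacks must be T x Y x X or T x Z x Y x X arrays", call. = FALSE)
  }
  nt <- dim(stack_num)[1L]
  proj <- function(stk, i) {
    if (nd == 3L) stk[i, , ] else apply(stk[i, , , , drop = TRUE], c(2L, 3L), max)
  }
  ny <- dim(stack_num)[nd - 1L]; nx <- dim(stack_num)[nd]
  get_mask <- function(i) {
    m <- if (length(dim(mask)) == 3L) mask[i, , ] else mask
    if (!identical(dim(m), c(ny, nx))) {
      stop("mask shape does not match the image frames", call. = FALSE)
    }
    m
  }
  if (is.null(t)) t <- (seq_len(nt) - 1L) * frame_interval
  num_mean <- den_mean <- floor_i <- numeric(nt)
  for (i in seq_len(nt)) {
    fn <- proj(stack_num, i); fd <- proj(stack_den, i)
    m <- get_mask(i)
    num_mean[i] <- mean(fn[m])
    den_mean[i] <- mean(fd[m])
    floor_i[i] <- if (is.null(den_floor)) {
      bg <- fd[!m]
      if (length(bg) > 1L) mean(bg) + 3 * sd(bg) else -Inf
    } else {
      den_floor
    }
  }
  valid <- den_mean > floor_i
  out <- data.frame(t = t, r = ifelse(valid, num_mean / den_mean, NA_real_),
                    num_mean = num_mean, den_mean = den_mean, valid = valid)
  attr(out, "cell_id") <- cell_id
  attr(out, "channel_pair") <- channel_pair
  class(out) <- c("ratio_trace", "data.frame")
  out
}

#' Construct a ratio trace directly from per-frame channel means
#'
#' Convenience constructor for workflows where channel means are already
#' extracted (e.g. the synthetic energy generator, or tabulated exports).
#'
#' @param t frame times, seconds.
#' @param num,den per-frame channel means (same length as `t`); or pass
#'   `r` directly.
#' @param r per-frame ratio; overrides `num`/`den` when given.
#' @inheritParams compute_ratio_trace
#' @export
ratio_trace <- function(t, num = NULL, den = NULL, r = NULL,
                        cell_id = "cell", channel_pair = c(482, 430)) {
  if (is.null(r)) {
    if (is.null(num) || is.null(den)) {
      stop("supply either `r` or both `num` and `den`", call. = FALSE)
    }
    r <- num / den
  } else {
    if (is.null(num)) num <- r
    if (is.null(den)) den <- rep(1, length(r))
  }
  if (length(t) != length(r)) stop("`t` and ratio length differ", call. = FALSE)
  out <- data.frame(t = t, r = r, num_mean = num, den_mean = den,
                    valid = is.finite(r))
  attr(out, "cell_id") <- cell_id
  attr(out, "channel_pair") <- channel_pair
  class(out) <- c("ratio_trace", "data.frame")
  out
}

#' Stationary baseline of a ratio trace
#'
#' The mean ratio over all valid frames lying in stationary phases across
#' the entire movie of one cell. This is the reference level from which
#' per-phase charges are measured.
#'
#' @param trace a `"ratio_trace"`.
#' @param seg the cell's [segment_phases()] result.
#' @return scalar baseline (ratio units).
#' @export
stationary_baseline <- function(trace, seg) {
  stopifnot(inherits(trace, "ratio_trace"))
  stat <- seg[seg$state == "STAT", , drop = FALSE]
  if (!nrow(stat)) {
    stop("no stationary phase: baseline undefined", call. = FALSE)
  }
  in_stat <- rep(FALSE, nrow(trace))
  for (k in seq_len(nrow(stat))) {
    in_stat <- in_stat | (trace$t >= stat$t_start[k] &
                            trace$t <= stat$t_end[k])
  }
  sel <- in_stat & trace$valid
  if (!any(sel)) stop("no valid frames in stationary phases", call. = FALSE)
  mean(trace$r[sel])
}

#' Per-phase charge: baseline-relative area under the ratio curve per unit
#' time
#'
#' For each phase the trapezoidal integral of `r - baseline` over
#' `[t_start, t_end]` is divided by the phase duration. Phase-boundary
#' values are obtained by linear interpolation between the bracketing
#' frames, which makes the integral exact for piecewise-linear traces
#' sampled at their breakpoints and additive across adjacent phases.
#' Dips of the ratio below baseline give negative charge.
#'
#' @param trace a `"ratio_trace"`.
#' @param seg a [segment_phases()] result covering the trace.
#' @param baseline reference ratio; defaults to
#'   [stationary_baseline()] of the same trace and segmentation.
#' @return data.frame of class `"charge_result"`: `state`, `t_start`,
#'   `t_end`, `duration`, `auc` (ratio units x s), `charge` (ratio units;
#'   `NA` with `flagged = TRUE` for phases shorter than one frame
#'   interval), with attributes `baseline` and `cell_id`.
#' @export
phase_charge <- function(trace, seg, baseline = NULL) {
  stopifnot(inherits(trace, "ratio_trace"))
  if (is.null(baseline)) baseline <- stationary_baseline(trace, seg)
  ok <- trace$valid & is.finite(trace$r)
  tt <- trace$t[ok]; rr <- trace$r[ok]
  if (length(tt) < 2L) stop("not enough valid frames", call. = FALSE)
  min_dt <- min(diff(tt))
  n <- nrow(seg)
  auc <- dur <- charge <- rep(NA_real_, n)
  flagged <- rep(FALSE, n)
  for (k in seq_len(n)) {
    a <- seg$t_start[k]; b <- seg$t_end[k]
    dur[k] <- b - a
    if (dur[k] < min_dt) {
      flagged[k] <- TRUE
      next
    }
    inside <- tt > a & tt < b
    xs <- c(a, tt[inside], b)
    ys <- c(approx_ratio(tt, rr, a), rr[inside], approx_ratio(tt, rr, b))
    auc[k] <- pracma::trapz(xs, ys - baseline)
    charge[k] <- auc[k] / dur[k]
  }
  out <- data.frame(state = seg$state, t_start = seg$t_start,
                    t_end = seg$t_end, duration = dur, auc = auc,
                    charge = charge, flagged = flagged,
                    stringsAsFactors = FALSE)
  attr(out, "baseline") <- baseline
  attr(out, "cell_id") <- attr(trace, "cell_id")
  class(out) <- c("charge_result", "data.frame")
  out
}

# linear interpolation clamped to the sampled range
approx_ratio <- function(tt, rr, x) {
  if (x <= tt[1L]) return(rr[1L])
  if (x >= tt[length(tt)]) return(rr[length(tt)])
  stats::approx(tt, rr, xout = x)$y
}

#' Normalise a ratio trace to its per-cell maximum
#'
#' Expresses the trace as a percentage with 100 at the cell's highest valid
#' ratio, the convention used to put pH and ATP/ADP sensors on a common
#' scale.
#'
#' @param trace a `"ratio_trace"`.
#' @return the trace with an added column `r_pct`.
#' @export
percent_normalize <- function(trace) {
  stopifnot(inherits(trace, "ratio_trace"))
  sel <- trace$valid & is.finite(trace$r)
  if (!any(sel)) stop("no valid frames to normalise", call. = FALSE)
  trace$r_pct <- 100 * trace$r / max(trace$r[sel])
  trace
}

#' Summarise per-cell ratios by experimental condition
#'
#' @param data data.frame with one row per cell, columns `condition` and
#'   `ratio` (e.g. each cell's mean sensor ratio under DMSO or increasing
#'   rotenone doses).
#' @return data.frame with one row per non-empty condition: `condition`,
#'   `n`, `mean`, `sem`. Conditions present as factor levels but without
#'   observations are dropped with a warning.
#' @export
condition_ratio_summary <- function(data) {
  stopifnot(all(c("condition", "ratio") %in% names(data)))
  cond <- data$condition
  all_levels <- if (is.factor(cond)) levels(cond) else unique(as.character(cond))
  empty <- setdiff(all_levels, unique(as.character(cond)))
  if (length(empty)) {
    warning(sprintf("empty condition(s) omitted: %s",
                    paste(empty, collapse = ", ")), call. = FALSE)
  }
  parts <- split(data$ratio, as.character(cond))
  out <- data.frame(
    condition = names(parts),
    n = vapply(parts, length, integer(1)),
    mean = vapply(parts, mean, numeric(1)),
    sem = vapply(parts, function(x) {
      if (length(x) > 1L) sd(x) / sqrt(length(x)) else 0
    }, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out[match(unique(as.character(cond)), out$condition), , drop = FALSE]
}
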