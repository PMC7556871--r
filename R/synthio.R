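#' Parameters for the two-state saltatory trajectory generator
#'
#' Saltatory migration is modelled as a memoryless two-state (migratory /
#' stationary) alternating renewal process: dwell times are exponential,
#' so the long-run migratory fraction ("duty cycle") equals
#' `mean_phase_mig / (mean_phase_mig + mean_phase_stat)`. Within a frame
#' interval the cell advances at the state speed along a persistent heading
#' with Gaussian positional jitter.
#'
#' Defaults are scaled to wild-type RMS neuroblasts: migratory speed around
#' 116 um/h, roughly 48 percent of the hour spent migrating, movies of 1 h
#' at one frame per 30 s.
#'
#' @param frame_interval seconds between frames.
#' @param duration movie duration in seconds.
#' @param v_mig mean migratory-state speed, um/h.
#' @param v_noise positional jitter expressed as a speed SD (um/h) applied
#'   per coordinate in both states; 10 um/h at 30 s frames corresponds to
#'   about 0.08 um of centroid jitter per frame.
#' @param duty_cycle long-run migratory fraction in \[0, 1\].
#' @param mean_phase_mig mean migratory dwell, seconds.
#' @param mean_phase_stat mean stationary dwell, seconds; derived from
#'   `duty_cycle` and `mean_phase_mig` when `NULL`.
#' @param turn_sd SD of the per-frame heading change, radians.
#' @param min_dwell_frames minimum dwell in frames (phases shorter than the
#'   sampling resolution are not representable).
#' @param seed RNG seed (mandatory; generators never touch global state).
#' @return a validated parameter list of class `"saltatory_params"`.
#' @export
saltatory_params <- function(frame_interval = 30, duration = 3600,
                             v_mig = 116.2, v_noise = 10,
                             duty_cycle = 0.478,
                             mean_phase_mig = 480,
                             mean_phase_stat = NULL,
                             turn_sd = 0.15, min_dwell_frames = 2L,
                             seed = 1L) {
  stopifnot_scalar(frame_interval, "frame_interval", positive = TRUE)
  stopifnot_scalar(duration, "duration", positive = TRUE)
  stopifnot_scalar(v_mig, "v_mig", nonneg = TRUE)
  stopifnot_scalar(v_noise, "v_noise", nonneg = TRUE)
  stopifnot_fraction(duty_cycle, "duty_cycle")
  stopifnot_scalar(mean_phase_mig, "mean_phase_mig", positive = TRUE)
  stopifnot_scalar(turn_sd, "turn_sd", nonneg = TRUE)
  if (is.null(mean_phase_stat)) {
    mean_phase_stat <- if (duty_cycle %in% c(0, 1)) {
      Inf  # degenerate single-state processes never leave their state
    } else {
      mean_phase_mig * (1 - duty_cycle) / duty_cycle
    }
  }
  if (!(duty_cycle %in% c(0, 1))) {
    stopifnot_scalar(mean_phase_stat, "mean_phase_stat", positive = TRUE)
    implied <- mean_phase_mig / (mean_phase_mig + mean_phase_stat)
    if (abs(implied - duty_cycle) > 1e-9) {
      stop("duty_cycle inconsistent with mean dwell times", call. = FALSE)
    }
  }
  structure(
    list(frame_interval = frame_interval, duration = duration,
         v_mig = v_mig, v_noise = v_noise, duty_cycle = duty_cycle,
         mean_phase_mig = mean_phase_mig, mean_phase_stat = mean_phase_stat,
         turn_sd = turn_sd, min_dwell_frames = as.integer(min_dwell_frames),
         seed = seed),
    class = "saltatory_params"
  )
}

# Draw an alternating MIG/STAT state sequence over `n_int` frame intervals.
# Dwells are exponential in seconds, quantised to frames with a minimum
# dwell, so ground-truth phase boundaries always fall on the frame grid.
draw_states <- function(p, n_int) {
  if (p$duty_cycle == 0) return(rep("STAT", n_int))
  if (p$duty_cycle == 1) return(rep("MIG", n_int))
  state <- if (runif(1) < p$duty_cycle) "MIG" else "STAT"
  out <- character(0)
  while (length(out) < n_int) {
    mu <- if (state == "MIG") p$mean_phase_mig else p$mean_phase_stat
    dwell <- max(round(rexp(1, 1 / mu) / p$frame_interval),
                 p$min_dwell_frames)
    out <- c(out, rep(state, dwell))
    state <- if (state == "MIG") "STAT" else "MIG"
  }
  out[seq_len(n_int)]
}

# Collapse a per-interval state vector into (state, t_start, t_end) runs.
states_to_phases <- function(states, frame_t) {
  r <- rle(states)
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  data.frame(state = r$values,
             t_start = frame_t[starts],
             t_end = frame_t[ends + 1L],
             stringsAsFactors = FALSE)
}

#' Simulate a saltatory trajectory with ground truth
#'
#' Draws an alternating migratory/stationary state sequence (exponential
#' dwell times quantised to the frame grid), then integrates per-frame
#' displacements: the state speed along a slowly turning heading plus
#' isotropic Gaussian jitter. Deterministic for a fixed seed.
#'
#' @param params a [saltatory_params()] object.
#' @param cell_id id attached to the returned trajectory.
#' @return a list with elements
#'   \describe{
#'     \item{traj}{a [trajectory()];}
#'     \item{truth}{list with `states` (per frame interval, `"MIG"`/`"STAT"`),
#'       `phases` (data.frame `state`, `t_start`, `t_end`) and
#'       `migratory_fraction` (fraction of intervals in MIG).}
#'   }
#' @export
simulate_trajectory <- function(params, cell_id = "synth") {
  stopifnot(inherits(params, "saltatory_params"))
  p <- params
  n_int <- floor(p$duration / p$frame_interval)
  if (n_int < 1L) stop("duration shorter than one frame interval",
                       call. = FALSE)
  with_seed(p$seed, {
    states <- draw_states(p, n_int)
    dt <- p$frame_interval
    v_state <- ifelse(states == "MIG", p$v_mig, 0) / 3600  # um/s
    theta <- runif(1, 0, 2 * pi) + cumsum(rnorm(n_int, 0, p$turn_sd))
    jit_sd <- p$v_noise / 3600 * dt
    dx <- v_state * dt * cos(theta) + rnorm(n_int, 0, jit_sd)
    dy <- v_state * dt * sin(theta) + rnorm(n_int, 0, jit_sd)
    frame_t <- seq(0, by = dt, length.out = n_int + 1L)
    traj <- trajectory(t = frame_t,
                       x = c(0, cumsum(dx)), y = c(0, cumsum(dy)),
                       cell_id = cell_id, source = "synthio")
    list(traj = traj,
         truth = list(states = states,
                      phases = states_to_phases(states, frame_t),
                      migratory_fraction = mean(states == "MIG")))
  })
}

#' Parameters for the coupled ATP/ADP biosensor model
#'
#' The ratio dynamics observed in migrating neuroblasts — a decline in the
#' ATP/ADP ratio shortly after migratory onset and a progressive recovery
#' during stationary pauses — are emulated with the simplest model that has
#' those features: piecewise-linear decay at `drop_rate` during migratory
#' intervals and recovery at `recovery_rate` during stationary intervals,
#' clipped to `[r_floor, r0]`. Linearity makes the per-phase charge
#' analytically checkable.
#'
#' @param r0 stationary steady-state ratio (dimensionless).
#' @param drop_rate ratio units lost per second while migrating.
#' @param recovery_rate ratio units regained per second while stationary.
#' @param r_floor lower clip for the ratio; must be `< r0`.
#' @param noise_sd per-frame Gaussian noise on the rendered channels,
#'   expressed in ratio units.
#' @param den_level mean intensity (counts) of the denominator channel used
#'   when rendering the two excitation channels.
#' @param seed RNG seed.
#' @export
energy_params <- function(r0 = 1, drop_rate = 1.5e-5,
                          recovery_rate = 6e-5, r_floor = 0.7,
                          noise_sd = 0.01, den_level = 1000, seed = 1L) {
  stopifnot_scalar(r0, "r0")
  stopifnot_scalar(drop_rate, "drop_rate", nonneg = TRUE)
  stopifnot_scalar(recovery_rate, "recovery_rate", nonneg = TRUE)
  stopifnot_scalar(r_floor, "r_floor")
  stopifnot_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  stopifnot_scalar(den_level, "den_level", positive = TRUE)
  if (r_floor >= r0) stop("`r_floor` must be < `r0`", call. = FALSE)
  structure(list(r0 = r0, drop_rate = drop_rate,
                 recovery_rate = recovery_rate, r_floor = r_floor,
                 noise_sd = noise_sd, den_level = den_level, seed = seed),
            class = "energy_params")
}

#' Simulate a dual-excitation biosensor trace coupled to migration phases
#'
#' Integrates the piecewise-linear energy model over a per-interval state
#' sequence and emits the two excitation channels whose mean-intensity
#' ratio equals the clean model ratio before noise. Channel noise is added
#' independently per channel (SD `noise_sd * den_level / sqrt(2)` each, so
#' the ratio noise is approximately `noise_sd` for ratios near 1).
#'
#' @param states character vector of `"MIG"`/`"STAT"` per frame interval
#'   (e.g. `truth$states` from [simulate_trajectory()]).
#' @param params an [energy_params()] object.
#' @param frame_interval seconds per frame interval.
#' @return list with `trace` (data.frame `t`, `num`, `den`: channel mean
#'   intensities at frame times, one more row than intervals) and `truth`
#'   (list with `r_clean`, the noiseless ratio at frame times).
#' @export
simulate_energy_trace <- function(states, params, frame_interval = 30) {
  stopifnot(inherits(params, "energy_params"))
  if (length(states) < 1L) stop("empty phase sequence", call. = FALSE)
  if (!all(states %in% c("MIG", "STAT"))) {
    stop("states must be 'MIG' or 'STAT'", call. = FALSE)
  }
  stopifnot_scalar(frame_interval, "frame_interval", positive = TRUE)
  p <- params
  n <- length(states)
  r <- numeric(n + 1L)
  r[1L] <- p$r0
  for (i in seq_len(n)) {
    rate <- if (states[i] == "MIG") -p$drop_rate else p$recovery_rate
    r[i + 1L] <- min(max(r[i] + rate * frame_interval, p$r_floor), p$r0)
  }
  t <- seq(0, by = frame_interval, length.out = n + 1L)
  with_seed(p$seed, {
    sd_ch <- p$noise_sd * p$den_level / sqrt(2)
    den <- p$den_level + rnorm(n + 1L, 0, sd_ch)
    num <- r * p$den_level + rnorm(n + 1L, 0, sd_ch)
    list(trace = data.frame(t = t, num = num, den = den),
         truth = list(r_clean = r))
  })
}

#' Render a biosensor trace as two single-wavelength image stacks
#'
#' Produces co-registered T x Y x X stacks for the numerator and
#' denominator excitation channels: uniform intensity equal to the per-frame
#' channel mean inside a disk-shaped cell, `background` outside. The
#' channel-mean ratio inside the mask therefore equals `trace$num/trace$den`
#' exactly, which makes the stack a round-trip oracle for
#' [compute_ratio_trace()].
#'
#' @param trace data.frame with columns `num`, `den` (from
#'   [simulate_energy_trace()]).
#' @param shape `c(ny, nx)` image size in pixels.
#' @param cell_radius disk radius in pixels.
#' @param background intensity outside the cell.
#' @return list with `num`, `den` (arrays T x Y x X) and `mask`
#'   (logical Y x X).
#' @export
render_energy_stack <- function(trace, shape = c(32L, 32L),
                                cell_radius = 10, background = 10) {
  stopifnot(all(c("num", "den") %in% names(trace)))
  ny <- shape[1L]; nx <- shape[2L]
  cy <- (ny + 1) / 2; cx <- (nx + 1) / 2
  d2 <- outer((seq_len(ny) - cy)^2, (seq_len(nx) - cx)^2, `+`)
  mask <- d2 <= cell_radius^2
  nt <- nrow(trace)
  mk <- function(vals) {
    stk <- array(background, dim = c(nt, ny, nx))
    for (i in seq_len(nt)) {
      frame <- matrix(background, ny, nx)
      frame[mask] <- vals[i]
      stk[i, , ] <- frame
    }
    stk
  }
  list(num = mk(trace$num), den = mk(trace$den), mask = mask)
}

#' Parameters for synthetic tandem-reporter puncta scenes
#'
#' Emulates two-channel fields of autophagic vesicles as imaged with a
#' tandem RFP-GFP-LC3 reporter: every punctum is present in the RFP
#' (detection) channel, and a fraction `frac_dual` — the autophagosome
#' fraction, in which GFP is not yet quenched — is also present in the GFP
#' channel. Spots are isotropic Gaussians of width `psf_sigma` placed
#' uniformly at random subject to a minimum separation (default
#' `4 * psf_sigma`) so that ground-truth identity is unambiguous.
#'
#' @param image_shape `c(ny, nx)` pixels.
#' @param pixel_size um per pixel (metadata; scene geometry is in pixels).
#' @param n_puncta number of true puncta.
#' @param frac_dual probability that a punctum is GFP-positive.
#' @param psf_sigma Gaussian spot SD in pixels.
#' @param peak_snr spot peak amplitude divided by the background noise SD.
#' @param background mean background intensity.
#' @param noise_sd Gaussian read-noise SD.
#' @param min_sep minimum centre-to-centre distance in pixels.
#' @param seed RNG seed.
#' @export
puncta_scene_params <- function(image_shape = c(128L, 128L),
                                pixel_size = 0.25, n_puncta = 80L,
                                frac_dual = 0.355, psf_sigma = 1.5,
                                peak_snr = 5, background = 100,
                                noise_sd = 10, min_sep = NULL, seed = 1L) {
  stopifnot_scalar(n_puncta, "n_puncta", nonneg = TRUE)
  stopifnot_fraction(frac_dual, "frac_dual")
  stopifnot_scalar(psf_sigma, "psf_sigma", positive = TRUE)
  stopifnot_scalar(peak_snr, "peak_snr", positive = TRUE)
  stopifnot_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  if (is.null(min_sep)) min_sep <- 4 * psf_sigma
  structure(list(image_shape = as.integer(image_shape),
                 pixel_size = pixel_size, n_puncta = as.integer(n_puncta),
                 frac_dual = frac_dual, psf_sigma = psf_sigma,
                 peak_snr = peak_snr, background = background,
                 noise_sd = noise_sd, min_sep = min_sep, seed = seed),
            class = "puncta_scene_params")
}

# Uniform positions with a minimum pairwise separation, by bounded
# rejection sampling (1000 retries per point before giving up).
sample_separated <- function(n, ny, nx, min_sep, margin, retries = 1000L) {
  ys <- numeric(0); xs <- numeric(0)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (k in seq_len(retries)) {
      y <- runif(1, 1 + margin, ny - margin)
      x <- runif(1, 1 + margin, nx - margin)
      if (!length(ys) || all((ys - y)^2 + (xs - x)^2 >= min_sep^2)) {
        ys <- c(ys, y); xs <- c(xs, x); placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("puncta density too high for the minimum-separation constraint",
           call. = FALSE)
    }
  }
  cbind(y = ys, x = xs)
}

add_gaussian_spots <- function(img, pos, amp, sigma) {
  if (!nrow(pos)) return(img)
  ny <- nrow(img); nx <- ncol(img)
  r <- ceiling(4 * sigma)
  for (i in seq_len(nrow(pos))) {
    y0 <- pos[i, 1L]; x0 <- pos[i, 2L]
    yy <- max(1L, floor(y0 - r)):min(ny, ceiling(y0 + r))
    xx <- max(1L, floor(x0 - r)):min(nx, ceiling(x0 + r))
    g <- amp[i] * outer(exp(-(yy - y0)^2 / (2 * sigma^2)),
                        exp(-(xx - x0)^2 / (2 * sigma^2)))
    img[yy, xx] <- img[yy, xx] + g
  }
  img
}

#' Render a two-channel puncta scene with ground truth
#'
#' @param params a [puncta_scene_params()] object.
#' @return list with `rfp`, `gfp` (matrices Y x X) and `truth`, a
#'   data.frame with `id`, `y`, `x` (true sub-pixel centres) and `dual`
#'   (logical, GFP-positive).
#' @export
render_puncta_stack <- function(params) {
  stopifnot(inherits(params, "puncta_scene_params"))
  p <- params
  ny <- p$image_shape[1L]; nx <- p$image_shape[2L]
  with_seed(p$seed, {
    pos <- if (p$n_puncta > 0L) {
      sample_separated(p$n_puncta, ny, nx, p$min_sep,
                       margin = ceiling(3 * p$psf_sigma))
    } else {
      matrix(numeric(0), 0L, 2L, dimnames = list(NULL, c("y", "x")))
    }
    dual <- if (p$n_puncta > 0L) {
      as.logical(rbinom(p$n_puncta, 1L, p$frac_dual))
    } else {
      logical(0)
    }
    amp <- rep(p$peak_snr * p$noise_sd, p$n_puncta)
    rfp <- add_gaussian_spots(matrix(p$background, ny, nx), pos, amp,
                              p$psf_sigma)
    gfp <- add_gaussian_spots(matrix(p$background, ny, nx),
                              pos[dual, , drop = FALSE], amp[dual],
                              p$psf_sigma)
    if (p$noise_sd > 0) {
      rfp <- rfp + matrix(rnorm(ny * nx, 0, p$noise_sd), ny, nx)
      gfp <- gfp + matrix(rnorm(ny * nx, 0, p$noise_sd), ny, nx)
    }
    truth <- data.frame(id = seq_len(p$n_puncta),
                        y = pos[, "y"], x = pos[, "x"], dual = dual)
    list(rfp = rfp, gfp = gfp, truth = truth)
  })
}

#' Simulate per-frame puncta counts coupled to migration phases
#'
#' Emulates the phase-resolved autophagosome density readout: the count of
#' RFP-positive puncta per frame is Poisson with a state-dependent density,
#' the migratory-state density being `rel_density_mig` times the stationary
#' one (defaults mirror the observed two-thirds contrast).
#'
#' @param states per-interval `"MIG"`/`"STAT"` vector.
#' @param frame_interval seconds per interval.
#' @param density_stat stationary-state density, puncta per um^2.
#' @param rel_density_mig migratory density relative to stationary.
#' @param area_um2 visible cell area per frame.
#' @param seed RNG seed.
#' @return list with `counts` (data.frame `frame`, `t`, `n_puncta`,
#'   `area_um2`, one row per frame) and `truth` (the programmed per-state
#'   densities).
#' @export
simulate_puncta_counts <- function(states, frame_interval = 30,
                                   density_stat = 0.5,
                                   rel_density_mig = 0.66,
                                   area_um2 = 120, seed = 1L) {
  if (length(states) < 1L) stop("empty phase sequence", call. = FALSE)
  stopifnot_scalar(density_stat, "density_stat", positive = TRUE)
  stopifnot_scalar(rel_density_mig, "rel_density_mig", nonneg = TRUE)
  n_frames <- length(states) + 1L
  # frame i sits between intervals i-1 and i; use the following interval's
  # state (last frame inherits the final interval's state)
  frame_state <- c(states, states[length(states)])
  dens <- ifelse(frame_state == "MIG", density_stat * rel_density_mig,
                 density_stat)
  with_seed(seed, {
    counts <- rpois(n_frames, dens * area_um2)
    list(counts = data.frame(frame = seq_len(n_frames),
                             t = (seq_len(n_frames) - 1L) * frame_interval,
                             n_puncta = counts, area_um2 = area_um2),
         truth = list(density_stat = density_stat,
                      density_mig = density_stat * rel_density_mig))
  })
}

# Assign every pixel of an image to (arc length along path, distance to
# path), using nearest-point projection onto the polyline segments.
# `path` is a matrix with columns x, y in pixel coordinates.
arc_assign <- function(ny, nx, path) {
  px <- rep(seq_len(nx), each = ny)
  py <- rep(seq_len(ny), times = nx)
  nseg <- nrow(path) - 1L
  seglen <- sqrt(diff(path[, 1L])^2 + diff(path[, 2L])^2)
  cum0 <- c(0, cumsum(seglen))
  best_d2 <- rep(Inf, ny * nx)
  best_arc <- rep(NA_real_, ny * nx)
  for (j in seq_len(nseg)) {
    ax <- path[j, 1L]; ay <- path[j, 2L]
    bx <- path[j + 1L, 1L]; by <- path[j + 1L, 2L]
    l2 <- (bx - ax)^2 + (by - ay)^2
    tt <- pmin(1, pmax(0, ((px - ax) * (bx - ax) + (py - ay) * (by - ay)) / l2))
    d2 <- (px - (ax + tt * (bx - ax)))^2 + (py - (ay + tt * (by - ay)))^2
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_arc[upd] <- cum0[j] + tt[upd] * seglen[j]
  }
  list(arc = matrix(best_arc, ny, nx), dist = matrix(sqrt(best_d2), ny, nx))
}

#' Render a leading-process image with a programmed intensity gradient
#'
#' Draws a gently curved tube (the leading process) emanating from a
#' disk-shaped soma, with the mean intensity of each consecutive arc-length
#' bin set to the requested values. The tube geometry and the per-pixel
#' bin assignment are exported so profile recovery can be verified exactly.
#'
#' @param bin_means per-bin true mean intensities, ordered from the soma
#'   outward (>= 1 bin).
#' @param soma_mean true soma intensity.
#' @param pixel_size um per pixel.
#' @param bin_width_um arc-length bin width in um (default 20).
#' @param tube_width_px full tube width in pixels.
#' @param soma_radius_px soma disk radius in pixels.
#' @param background baseline intensity added everywhere (structures sit
#'   on top of it, as a fluorescence background would).
#' @param noise_sd Gaussian noise SD added everywhere.
#' @param curvature heading change per path step, radians.
#' @param seed RNG seed.
#' @return list with `image` (Y x X matrix), `path` (matrix of x, y pixel
#'   coordinates starting at the soma boundary), `soma_mask` (logical
#'   matrix), `pixel_size`, and `truth` (list with `bin_means`,
#'   `soma_mean`).
#' @export
render_process_image <- function(bin_means, soma_mean, pixel_size = 0.5,
                                 bin_width_um = 20, tube_width_px = 6,
                                 soma_radius_px = 12, background = 0,
                                 noise_sd = 0, curvature = 0.01,
                                 seed = 1L) {
  if (length(bin_means) < 1L) stop("need at least one bin", call. = FALSE)
  stopifnot_scalar(pixel_size, "pixel_size", positive = TRUE)
  stopifnot_scalar(bin_width_um, "bin_width_um", positive = TRUE)
  n_bins <- length(bin_means)
  path_len_px <- n_bins * bin_width_um / pixel_size
  step <- 2  # px per path vertex
  n_step <- ceiling(path_len_px / step) + 2L  # overshoot, then trim
  # curved path from the soma boundary, heading east with constant turn
  theta <- 0.3 + curvature * step * (seq_len(n_step) - 1L)
  soma_c <- c(x = soma_radius_px + 6, y = 0)
  start <- soma_c + soma_radius_px * c(cos(theta[1L]), sin(theta[1L]))
  vx <- c(start[1L], start[1L] + cumsum(step * cos(theta)))
  vy <- c(start[2L], start[2L] + cumsum(step * sin(theta)))
  # trim to the exact requested arc length
  cum <- c(0, cumsum(sqrt(diff(vx)^2 + diff(vy)^2)))
  keep <- cum < path_len_px - 1e-9
  last <- max(which(keep))
  frac <- (path_len_px - cum[last]) / (cum[last + 1L] - cum[last])
  vx <- c(vx[keep], vx[last] + frac * (vx[last + 1L] - vx[last]))
  vy <- c(vy[keep], vy[last] + frac * (vy[last + 1L] - vy[last]))
  margin <- tube_width_px + 8
  x_off <- margin - min(c(vx, soma_c[1L] - soma_radius_px))
  y_off <- margin - min(c(vy, soma_c[2L] - soma_radius_px))
  vx <- vx + x_off; vy <- vy + y_off
  soma_c <- soma_c + c(x_off, y_off)
  nx <- ceiling(max(vx, soma_c[1L] + soma_radius_px) + margin)
  ny <- ceiling(max(vy, soma_c[2L] + soma_radius_px) + margin)
  path <- cbind(x = vx, y = vy)

  asn <- arc_assign(ny, nx, path)
  d2_soma <- outer((seq_len(ny) - soma_c[2L])^2,
                   (seq_len(nx) - soma_c[1L])^2, `+`)
  soma_mask <- d2_soma <= soma_radius_px^2
  bin_width_px <- bin_width_um / pixel_size
  bin_idx <- pmin(floor(asn$arc / bin_width_px) + 1L, n_bins)
  tube <- asn$dist <= tube_width_px / 2 & !soma_mask
  img <- matrix(background, ny, nx)
  img[tube] <- background + bin_means[bin_idx[tube]]
  img[soma_mask] <- background + soma_mean
  with_seed(seed, {
    if (noise_sd > 0) img <- img + matrix(rnorm(ny * nx, 0, noise_sd), ny, nx)
    list(image = img, path = path, soma_mask = soma_mask,
         pixel_size = pixel_size,
         truth = list(bin_means = bin_means, soma_mean = soma_mean))
  })
}
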