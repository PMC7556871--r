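# 2D convolution with edge replication; kernel must be odd-sized
conv2_replicate <- function(img, kern) {
  kr <- (nrow(kern) - 1L) %/% 2L
  kc <- (ncol(kern) - 1L) %/% 2L
  ny <- nrow(img); nx <- ncol(img)
  pad <- matrix(0, ny + 2L * kr, nx + 2L * kc)
  pad[(kr + 1L):(kr + ny), (kc + 1L):(kc + nx)] <- img
  # replicate borders
  pad[1:kr, ] <- pad[rep(kr + 1L, kr), ]
  pad[(kr + ny + 1L):(ny + 2L * kr), ] <- pad[rep(kr + ny, kr), ]
  pad[, 1:kc] <- pad[, rep(kc + 1L, kc)]
  pad[, (kc + nx + 1L):(nx + 2L * kc)] <- pad[, rep(kc + nx, kc)]
  out <- matrix(0, ny, nx)
  for (i in seq_len(nrow(kern))) {
    for (j in seq_len(ncol(kern))) {
      w <- kern[i, j]
      if (w == 0) next
      out <- out + w * pad[(i):(i + ny - 1L), (j):(j + nx - 1L)]
    }
  }
  out
}

log_kernel <- function(sigma) {
  r <- ceiling(3.5 * sigma)
  xx <- -r:r
  g <- exp(-xx^2 / (2 * sigma^2))
  G <- outer(g, g)
  G <- G / sum(G)
  d2 <- outer(xx^2, xx^2, `+`)
  # scale-normalised negative LoG: positive response on bright blobs
  K <- -(d2 - 2 * sigma^2) / sigma^2 * G
  K - mean(K)  # zero-sum: flat background gives zero response
}

#' Detect fluorescent puncta in a single-channel frame
#'
#' Scale-matched blob detection: the frame is filtered with a
#' scale-normalised Laplacian-of-Gaussian kernel at the expected spot
#' width, local maxima of the response are thresholded at `k` robust noise
#' SDs (median absolute deviation of the response map), and peak positions
#' are optionally refined to sub-pixel precision by a quadratic fit.
#' Deterministic.
#'
#' The default `k = 5` sits above the expected extreme value of a smoothed
#' Gaussian noise field at these image sizes (about 4.5 SD for ~10^4-10^5
#' pixels), so structure-free frames yield no detections while spots at
#' peak SNR 5 are still recovered at high sensitivity after matched
#' filtering.
#'
#' @param image 2D numeric matrix (the detection channel, conventionally
#'   RFP for a tandem reporter — every vesicle carries RFP).
#' @param psf_sigma expected spot Gaussian SD in pixels.
#' @param k detection threshold in robust noise SDs.
#' @param refine logical, sub-pixel quadratic refinement.
#' @return data.frame of class `"puncta"`: `id`, `y`, `x`, `response`
#'   (LoG peak response), `peak` (raw image value at the peak pixel).
#' @export
detect_puncta <- function(image, psf_sigma, k = 5, refine = TRUE) {
  if (!is.matrix(image)) stop("`image` must be a matrix", call. = FALSE)
  stopifnot_scalar(psf_sigma, "psf_sigma", positive = TRUE)
  if (2 * ceiling(3.5 * psf_sigma) + 1 > min(dim(image))) {
    stop("`psf_sigma` too large for the image", call. = FALSE)
  }
  resp <- conv2_replicate(image, log_kernel(psf_sigma))
  noise_sd <- median(abs(resp - median(resp))) * 1.4826
  # absolute floor guards against numerical dust on structure-free frames
  thr <- max(k * noise_sd, 1e-8 * max(abs(image)), 1e-12)
  ny <- nrow(resp); nx <- ncol(resp)
  # local maxima over a scale-matched window (safe: scene generation
  # guarantees spot separations beyond it)
  w <- max(1L, ceiling(psf_sigma))
  core <- resp[(w + 1L):(ny - w), (w + 1L):(nx - w)]
  is_max <- core > thr
  for (dy in -w:w) for (dx in -w:w) {
    if (dy == 0 && dx == 0) next
    nb <- resp[(w + 1L):(ny - w) + dy, (w + 1L):(nx - w) + dx]
    is_max <- is_max & core >= nb
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (!nrow(idx)) {
    out <- data.frame(id = integer(0), y = numeric(0), x = numeric(0),
                      response = numeric(0), peak = numeric(0))
    class(out) <- c("puncta", "data.frame")
    return(out)
  }
  py <- idx[, 1L] + w; px <- idx[, 2L] + w
  yr <- as.numeric(py); xr <- as.numeric(px)
  if (refine) {
    for (i in seq_along(py)) {
      r0 <- resp[py[i], px[i]]
      dy <- resp[py[i] - 1L, px[i]] - 2 * r0 + resp[py[i] + 1L, px[i]]
      dx <- resp[py[i], px[i] - 1L] - 2 * r0 + resp[py[i], px[i] + 1L]
      if (dy < 0) {
        yr[i] <- py[i] + 0.5 * (resp[py[i] - 1L, px[i]] -
                                  resp[py[i] + 1L, px[i]]) / dy
      }
      if (dx < 0) {
        xr[i] <- px[i] + 0.5 * (resp[py[i], px[i] - 1L] -
                                  resp[py[i], px[i] + 1L]) / dx
      }
    }
  }
  ord <- order(-resp[cbind(py, px)])
  out <- data.frame(id = seq_along(ord), y = yr[ord], x = xr[ord],
                    response = resp[cbind(py, px)][ord],
                    peak = image[cbind(py, px)][ord])
  class(out) <- c("puncta", "data.frame")
  out
}

#' Label puncta by a secondary, co-registered channel
#'
#' Adds a logical label column (e.g. `gfp` for the tandem reporter's GFP
#' channel, or `lamp1` for lysosomal immunostaining) to detected puncta: a
#' punctum is positive when the mean secondary-channel intensity within a
#' radius-`rho` disk around it exceeds the background mean by `k` SDs of
#' that disk mean. Background level and pixel noise are estimated robustly
#' from the whole secondary frame (median and MAD — puncta occupy a small
#' fraction of the field).
#'
#' @param punctae a `"puncta"` data.frame from [detect_puncta()].
#' @param image_secondary matrix, same shape as the detection frame.
#' @param label name of the logical column to add (default `"gfp"`).
#' @param rho disk radius in pixels.
#' @param k threshold in SDs of the disk-mean statistic.
#' @return `punctae` with the new logical column.
#' @export
classify_secondary <- function(punctae, image_secondary, label = "gfp",
                               rho = 2, k = 3) {
  stopifnot(inherits(punctae, "puncta"))
  if (!is.matrix(image_secondary)) {
    stop("`image_secondary` must be a matrix", call. = FALSE)
  }
  ny <- nrow(image_secondary); nx <- ncol(image_secondary)
  bg_med <- median(image_secondary)
  bg_sd <- median(abs(image_secondary - bg_med)) * 1.4826
  pos <- logical(nrow(punctae))
  off <- expand.grid(dy = -ceiling(rho):ceiling(rho),
                     dx = -ceiling(rho):ceiling(rho))
  off <- off[off$dy^2 + off$dx^2 <= rho^2, ]
  for (i in seq_len(nrow(punctae))) {
    yy <- round(punctae$y[i]) + off$dy
    xx <- round(punctae$x[i]) + off$dx
    keep <- yy >= 1 & yy <= ny & xx >= 1 & xx <= nx
    vals <- image_secondary[cbind(yy[keep], xx[keep])]
    thr <- bg_med + k * bg_sd / sqrt(length(vals))
    pos[i] <- mean(vals) > thr
  }
  punctae[[label]] <- pos
  punctae
}

#' Percentage of autophagosomes among detected vesicles
#'
#' With a tandem RFP-GFP-LC3 reporter all vesicles are RFP-positive and
#' autophagosomes retain GFP, so the autophagosome percentage is
#' `100 * |GFP+ and RFP+| / |RFP+|`. Detection is performed on the RFP
#' channel, so every punctum in the input counts as RFP-positive.
#'
#' @param punctae a labelled `"puncta"` data.frame containing the logical
#'   column named in `label`.
#' @param label secondary label column (default `"gfp"`).
#' @return percentage in \[0, 100\]; `NA` with a warning when no puncta
#'   were detected.
#' @export
percent_autophagosome <- function(punctae, label = "gfp") {
  if (!nrow(punctae)) {
    warning("no RFP-positive puncta: percentage undefined", call. = FALSE)
    return(NA_real_)
  }
  if (is.null(punctae[[label]])) {
    stop(sprintf("punctae carry no '%s' label; run classify_secondary()",
                 label), call. = FALSE)
  }
  100 * sum(punctae[[label]]) / nrow(punctae)
}

#' Phase-resolved puncta density, normalised to the first stationary phase
#'
#' For each migration phase the vesicle density (count per unit cell area)
#' is sampled at three time points — the beginning, middle and end of the
#' phase (middle frame = floor of the phase midpoint) — and averaged.
#' All phase densities are then expressed as a percentage of the first
#' stationary phase's density, which is 100 by construction.
#'
#' @param counts data.frame with one row per frame: columns `t` (s),
#'   `n_puncta`, `area_um2` (e.g. from [simulate_puncta_counts()] or a
#'   per-frame detection loop).
#' @param seg a [segment_phases()]-style phase table for the same movie.
#' @return data.frame: `state`, `t_start`, `t_end`, `density`
#'   (puncta/um^2), `density_norm_pct`, `flagged` (TRUE when a phase held
#'   fewer than 3 frames and fewer samples were used).
#' @export
phase_density <- function(counts, seg) {
  stopifnot(all(c("t", "n_puncta", "area_um2") %in% names(counts)))
  n <- nrow(seg)
  dens <- rep(NA_real_, n)
  flagged <- rep(FALSE, n)
  for (kk in seq_len(n)) {
    # half-open membership: a frame on a phase boundary belongs to the
    # phase beginning there (the final phase keeps its end frame)
    in_ph <- which(counts$t >= seg$t_start[kk] &
                     (counts$t < seg$t_end[kk] | kk == n))
    if (!length(in_ph)) {
      flagged[kk] <- TRUE
      next
    }
    if (length(in_ph) < 3L) {
      pick <- in_ph
      flagged[kk] <- TRUE
    } else {
      first <- in_ph[1L]; last <- in_ph[length(in_ph)]
      mid <- floor((first + last) / 2)
      pick <- c(first, mid, last)
    }
    dens[kk] <- mean(counts$n_puncta[pick] / counts$area_um2[pick])
  }
  first_stat <- which(seg$state == "STAT" & !is.na(dens))[1L]
  if (is.na(first_stat)) {
    stop("no stationary phase: density normalisation undefined",
         call. = FALSE)
  }
  data.frame(state = seg$state, t_start = seg$t_start, t_end = seg$t_end,
             density = dens,
             density_norm_pct = 100 * dens / dens[first_stat],
             flagged = flagged, stringsAsFactors = FALSE)
}

# bilinear interpolation of a matrix at real-valued (y, x) positions
bilinear <- function(img, y, x) {
  ny <- nrow(img); nx <- ncol(img)
  y <- pmin(pmax(y, 1), ny); x <- pmin(pmax(x, 1), nx)
  y0 <- pmin(floor(y), ny - 1L); x0 <- pmin(floor(x), nx - 1L)
  fy <- y - y0; fx <- x - x0
  img[cbind(y0, x0)] * (1 - fy) * (1 - fx) +
    img[cbind(y0 + 1L, x0)] * fy * (1 - fx) +
    img[cbind(y0, x0 + 1L)] * (1 - fy) * fx +
    img[cbind(y0 + 1L, x0 + 1L)] * fy * fx
}

#' Kymograph of a time-lapse stack along a traced path
#'
#' Samples each frame along the polyline at 1-pixel arc-length steps,
#' taking the maximum over a short perpendicular profile of width `width`
#' pixels, and stacks the samples into an arc-length x time matrix.
#' A vesicle moving along the path at constant speed appears as a straight
#' sloped line whose slope is its speed.
#'
#' @param stack numeric array `T x Y x X`.
#' @param path matrix with columns `x`, `y`: polyline in pixel
#'   coordinates (>= 2 points).
#' @param width perpendicular sampling width in pixels (odd).
#' @return matrix with one row per arc-length step and one column per
#'   frame; attribute `arc_px` holds the arc positions.
#' @export
kymograph <- function(stack, path, width = 3) {
  if (length(dim(stack)) != 3L) stop("`stack` must be T x Y x X",
                                     call. = FALSE)
  if (is.null(dim(path)) || nrow(path) < 2L) {
    stop("degenerate path: need at least 2 points", call. = FALSE)
  }
  seglen <- sqrt(diff(path[, 1L])^2 + diff(path[, 2L])^2)
  cum <- c(0, cumsum(seglen))
  total <- cum[length(cum)]
  arc <- seq(0, total, by = 1)
  sx <- stats::approx(cum, path[, 1L], xout = arc)$y
  sy <- stats::approx(cum, path[, 2L], xout = arc)$y
  # unit tangents by central differences, then perpendiculars
  tx <- c(diff(sx)[1L], (sx[-(1:2)] - sx[1:(length(sx) - 2L)]) / 2,
          diff(sx)[length(sx) - 1L])
  ty <- c(diff(sy)[1L], (sy[-(1:2)] - sy[1:(length(sy) - 2L)]) / 2,
          diff(sy)[length(sy) - 1L])
  nrm <- sqrt(tx^2 + ty^2)
  px <- -ty / nrm; py <- tx / nrm
  half <- (width - 1) / 2
  offsets <- seq(-half, half, by = 1)
  nt <- dim(stack)[1L]
  out <- matrix(NA_real_, length(arc), nt)
  for (fi in seq_len(nt)) {
    frame <- stack[fi, , ]
    prof <- matrix(-Inf, length(arc), length(offsets))
    for (oi in seq_along(offsets)) {
      prof[, oi] <- bilinear(frame, sy + offsets[oi] * py,
                             sx + offsets[oi] * px)
    }
    out[, fi] <- apply(prof, 1L, max)
  }
  attr(out, "arc_px") <- arc
  out
}

#' Match detected puncta to ground truth
#'
#' Greedy nearest-neighbour matching within a radius: candidate
#' detection-truth pairs are sorted by distance (ties by smaller truth id)
#' and accepted greedily, each detection and truth point at most once.
#'
#' @param detected data.frame with `y`, `x` (e.g. from [detect_puncta()]).
#' @param truth data.frame with `y`, `x` (e.g. a synthetic scene's truth).
#' @param radius maximum match distance in pixels.
#' @return list with `matches` (data.frame `det`, `truth`, `dist` of row
#'   indices), `precision`, `recall`, `f1`.
#' @export
match_puncta <- function(detected, truth, radius = 2) {
  nd <- nrow(detected); ntr <- nrow(truth)
  if (nd == 0L || ntr == 0L) {
    tp <- 0L
  } else {
    dmat <- sqrt(outer(detected$y, truth$y, `-`)^2 +
                   outer(detected$x, truth$x, `-`)^2)
    cand <- which(dmat <= radius, arr.ind = TRUE)
    ord <- order(dmat[cand], cand[, 2L])
    cand <- cand[ord, , drop = FALSE]
    used_d <- logical(nd); used_t <- logical(ntr)
    pairs <- list()
    for (i in seq_len(nrow(cand))) {
      d <- cand[i, 1L]; tr <- cand[i, 2L]
      if (used_d[d] || used_t[tr]) next
      used_d[d] <- TRUE; used_t[tr] <- TRUE
      pairs[[length(pairs) + 1L]] <- data.frame(det = d, truth = tr,
                                                dist = dmat[d, tr])
    }
    matches <- if (length(pairs)) do.call(rbind, pairs) else
      data.frame(det = integer(0), truth = integer(0), dist = numeric(0))
    tp <- nrow(matches)
  }
  if (!exists("matches", inherits = FALSE)) {
    matches <- data.frame(det = integer(0), truth = integer(0),
                          dist = numeric(0))
  }
  precision <- if (nd > 0) tp / nd else NA_real_
  recall <- if (ntr > 0) tp / ntr else NA_real_
  f1 <- if (isTRUE(precision + recall > 0)) {
    2 * precision * recall / (precision + recall)
  } else {
    0
  }
  list(matches = matches, precision = precision, recall = recall, f1 = f1)
}
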