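# shared fixtures and independent oracles

# build a speed_trace object directly from per-interval speeds (um/h)
make_speed_trace <- function(v, dt = 30, cell_id = "cell") {
  n <- length(v)
  frame_t <- seq(0, by = dt, length.out = n + 1L)
  out <- data.frame(t_mid = frame_t[-(n + 1L)] + dt / 2, v = v)
  attr(out, "cell_id") <- cell_id
  attr(out, "frame_t") <- frame_t
  class(out) <- c("speed_trace", "data.frame")
  out
}

# random trajectory for kinematics property tests
random_trajectory <- function(n = 50, seed = 1, cell_id = "rnd") {
  set.seed(seed)
  trajectory(t = cumsum(runif(n, 5, 60)),
             x = cumsum(rnorm(n)), y = cumsum(rnorm(n)),
             cell_id = cell_id)
}

# brute-force kinematics oracles (independent of the package internals)
bf_path_length <- function(tr) {
  s <- 0
  for (i in 2:nrow(tr)) {
    s <- s + sqrt((tr$x[i] - tr$x[i - 1])^2 + (tr$y[i] - tr$y[i - 1])^2)
  }
  s
}
bf_speeds <- function(tr) {
  v <- numeric(nrow(tr) - 1)
  for (i in seq_along(v)) {
    d <- sqrt((tr$x[i + 1] - tr$x[i])^2 + (tr$y[i + 1] - tr$y[i])^2)
    v[i] <- d / (tr$t[i + 1] - tr$t[i]) * 3600
  }
  v
}

# interior phase-boundary times of a (state, t_start, t_end) table
phase_boundaries <- function(phases) {
  if (nrow(phases) < 2L) return(numeric(0))
  phases$t_start[-1L]
}

# boundary F1 with a +/- tol matching window (greedy nearest pairing)
boundary_f1 <- function(est, tru, tol = 30) {
  if (!length(est) && !length(tru)) return(1)
  if (!length(est) || !length(tru)) return(0)
  used <- logical(length(tru))
  tp <- 0L
  for (b in est) {
    d <- abs(tru - b)
    d[used] <- Inf
    j <- which.min(d)
    if (d[j] <= tol) {
      used[j] <- TRUE
      tp <- tp + 1L
    }
  }
  prec <- tp / length(est)
  rec <- tp / length(tru)
  if (tp == 0) 0 else 2 * prec * rec / (prec + rec)
}

# simulate one cell and segment it with defaults
segmented_cell <- function(seed, params = saltatory_params(seed = seed)) {
  sim <- simulate_trajectory(params, cell_id = paste0("c", seed))
  seg <- segment_phases(instantaneous_speed(sim$traj))
  list(sim = sim, seg = seg)
}
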