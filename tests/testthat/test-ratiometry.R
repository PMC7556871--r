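make_uniform_stack <- function(nt, ny, nx, inside, outside = 0,
                               mask = NULL) {
  if (is.null(mask)) {
    mask <- matrix(FALSE, ny, nx)
    mask[3:(ny - 2), 3:(nx - 2)] <- TRUE
  }
  stk <- array(outside, c(nt, ny, nx))
  for (i in seq_len(nt)) {
    fr <- matrix(outside, ny, nx)
    fr[mask] <- inside[min(i, length(inside))]
    stk[i, , ] <- fr
  }
  list(stack = stk, mask = mask)
}

test_that("ratio of channel means is exact on uniform cells", {
  num <- make_uniform_stack(4, 12, 12, inside = 2000, outside = 10)
  den <- make_uniform_stack(4, 12, 12, inside = 1000, outside = 10)
  tr <- compute_ratio_trace(num$stack, den$stack, num$mask)
  expect_equal(tr$r, rep(2, 4))
  expect_true(all(tr$valid))

  expect_error(compute_ratio_trace(num$stack, den$stack[, 1:6, ],
                                   num$mask), "shape")
  expect_error(compute_ratio_trace(num$stack, den$stack,
                                   matrix(TRUE, 5, 5)), "mask")
})

test_that("z-stacks are max-projected before the channel means", {
  # cell signal lives in one z-plane; max projection must find it
  nz <- 3
  num <- array(0, c(2, nz, 8, 8)); den <- array(0, c(2, nz, 8, 8))
  mask <- matrix(TRUE, 8, 8)
  for (i in 1:2) {
    num[i, 2, , ] <- 600
    den[i, 2, , ] <- 300
  }
  tr <- compute_ratio_trace(num, den, mask, den_floor = 0)
  expect_equal(tr$r, c(2, 2))
})

test_that("frames with a failing denominator are flagged, not dropped", {
  num <- make_uniform_stack(3, 10, 10, inside = c(2000, 2000, 2000),
                            outside = 10)
  den <- make_uniform_stack(3, 10, 10, inside = c(1000, 1, 1000),
                            outside = 10)
  tr <- compute_ratio_trace(num$stack, den$stack, num$mask, den_floor = 100)
  expect_equal(tr$valid, c(TRUE, FALSE, TRUE))
  expect_true(is.na(tr$r[2]))
  expect_equal(tr$r[c(1, 3)], c(2, 2))
  expect_equal(nrow(tr), 3L)
})

test_that("rendered synthetic channels reproduce the clean model ratio at zero noise", {
  states <- rep(c("MIG", "STAT"), times = c(25, 35))
  sim <- simulate_energy_trace(states, energy_params(noise_sd = 0, seed = 2))
  stk <- render_energy_stack(sim$trace, shape = c(24L, 24L),
                             cell_radius = 8, background = 5)
  tr <- compute_ratio_trace(stk$num, stk$den, stk$mask)
  expect_equal(tr$r, sim$truth$r_clean, tolerance = 1e-9)
})

test_that("the stationary baseline is the masked mean over stationary frames", {
  seg <- data.frame(state = c("STAT", "MIG"), t_start = c(0, 60),
                    t_end = c(60, 120))
  tr <- ratio_trace(t = c(0, 30, 60, 90, 120), r = c(1, 2, 1.2, 9, 9))
  # frames at t = 0, 30, 60 are stationary (boundary frame included)
  expect_equal(stationary_baseline(tr, seg), mean(c(1, 2, 1.2)))

  trc <- ratio_trace(t = seq(0, 120, 30), r = rep(1.5, 5))
  expect_equal(stationary_baseline(trc, seg), 1.5)

  seg_m <- data.frame(state = "MIG", t_start = 0, t_end = 120)
  expect_error(stationary_baseline(trc, seg_m), "no stationary phase")

  # brute-force oracle on a random trace
  set.seed(21)
  tt <- seq(0, 3600, by = 30)
  rr <- runif(length(tt), 0.8, 1.2)
  seg_r <- data.frame(state = rep(c("STAT", "MIG"), 3),
                      t_start = seq(0, 3000, by = 600),
                      t_end = seq(600, 3600, by = 600))
  trr <- ratio_trace(tt, r = rr)
  in_stat <- logical(length(tt))
  for (k in which(seg_r$state == "STAT")) {
    in_stat <- in_stat | (tt >= seg_r$t_start[k] & tt <= seg_r$t_end[k])
  }
  expect_equal(stationary_baseline(trr, seg_r), mean(rr[in_stat]),
               tolerance = 1e-12)
})

test_that("phase charge is exact on analytically solvable traces", {
  seg <- data.frame(state = c("STAT", "MIG"), t_start = c(0, 300),
                    t_end = c(300, 600))
  tt <- seq(0, 600, by = 30)

  # identically at baseline: zero charge everywhere
  tr0 <- ratio_trace(tt, r = rep(1.4, length(tt)))
  ch0 <- phase_charge(tr0, seg, baseline = 1.4)
  expect_equal(ch0$charge, c(0, 0))

  # constant offset of -0.1: charge is exactly -0.1
  tr1 <- ratio_trace(tt, r = rep(1.3, length(tt)))
  ch1 <- phase_charge(tr1, seg, baseline = 1.4)
  expect_equal(ch1$charge, c(-0.1, -0.1))

  # symmetric triangular dip of depth 0.2 spanning a phase: mean depth 0.1
  r_tri <- rep(1.4, length(tt))
  mig_idx <- which(tt >= 300 & tt <= 600)
  half <- (length(mig_idx) - 1) / 2
  r_tri[mig_idx] <- 1.4 - 0.2 * (1 - abs(seq(-half, half) / half))
  ch2 <- phase_charge(ratio_trace(tt, r = r_tri), seg, baseline = 1.4)
  expect_equal(ch2$charge[2], -0.1, tolerance = 1e-12)
  expect_equal(ch2$charge[1], 0)
})

test_that("charge is linear in the trace and invariant to constant shifts", {
  set.seed(31)
  tt <- seq(0, 1200, by = 30)
  rr <- 1.2 + cumsum(rnorm(length(tt), 0, 0.01))
  seg <- data.frame(state = c("STAT", "MIG", "STAT"),
                    t_start = c(0, 450, 840), t_end = c(450, 840, 1200))
  base <- stationary_baseline(ratio_trace(tt, r = rr), seg)
  ch <- phase_charge(ratio_trace(tt, r = rr), seg, baseline = base)

  # scaling (r - baseline) by c scales every charge by c
  c_scale <- 3.7
  r2 <- base + c_scale * (rr - base)
  ch2 <- phase_charge(ratio_trace(tt, r = r2), seg, baseline = base)
  expect_equal(ch2$charge, c_scale * ch$charge, tolerance = 1e-9)

  # adding a constant shifts the baseline equally: charges unchanged
  ch3 <- phase_charge(ratio_trace(tt, r = rr + 0.5), seg,
                      baseline = base + 0.5)
  expect_equal(ch3$charge, ch$charge, tolerance = 1e-12)

  # time-unit invariance: minutes instead of seconds
  ch4 <- phase_charge(ratio_trace(tt / 60, r = rr),
                      data.frame(state = seg$state,
                                 t_start = seg$t_start / 60,
                                 t_end = seg$t_end / 60),
                      baseline = base)
  expect_equal(ch4$charge, ch$charge, tolerance = 1e-12)
})

test_that("duration-weighted charges add up to the whole-movie AUC", {
  set.seed(17)
  tt <- seq(0, 3600, by = 30)
  rr <- 1 + cumsum(rnorm(length(tt), 0, 0.005))
  seg <- data.frame(state = rep(c("STAT", "MIG"), 4),
                    t_start = seq(0, 3150, by = 450),
                    t_end = seq(450, 3600, by = 450))
  tr <- ratio_trace(tt, r = rr)
  base <- stationary_baseline(tr, seg)
  ch <- phase_charge(tr, seg, baseline = base)
  total <- pracma::trapz(tt, rr - base)
  expect_equal(sum(ch$charge * ch$duration), total, tolerance = 1e-9)
})

test_that("percent normalisation puts the per-cell maximum at exactly 100", {
  tr <- ratio_trace(c(0, 30, 60), r = c(1, 2, 4))
  expect_equal(percent_normalize(tr)$r_pct, c(25, 50, 100))

  trc <- ratio_trace(c(0, 30, 60), r = rep(1.7, 3))
  expect_equal(percent_normalize(trc)$r_pct, rep(100, 3))

  set.seed(5)
  rr <- runif(50, 0.5, 3)
  trr <- percent_normalize(ratio_trace(seq(0, 1470, 30), r = rr))
  expect_equal(max(trr$r_pct), 100)
  expect_equal(order(trr$r_pct), order(rr))
})

test_that("condition summaries report mean, SEM, n and warn on empty groups", {
  d <- data.frame(condition = c("ctrl", "ctrl"), ratio = c(2, 2))
  s <- condition_ratio_summary(d)
  expect_equal(s$mean, 2)
  expect_equal(s$sem, 0)
  expect_equal(s$n, 2L)

  d2 <- data.frame(condition = factor(c("a", "a", "b", "b"),
                                      levels = c("a", "b", "c")),
                   ratio = c(1, 2, 3, 4))
  expect_warning(s2 <- condition_ratio_summary(d2), "empty")
  expect_equal(nrow(s2), 2L)

  # programmed decreasing dose response is recovered in order
  set.seed(8)
  doses <- c(dmso = 1.0, rot1 = 0.9, rot10 = 0.75, rot20 = 0.6)
  d3 <- do.call(rbind, lapply(names(doses), function(cn) {
    data.frame(condition = cn, ratio = rnorm(12, doses[[cn]], 0.02))
  }))
  s3 <- condition_ratio_summary(d3)
  expect_equal(s3$condition, names(doses))
  expect_true(all(diff(s3$mean) < 0))
})
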