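test_that("saltatory parameter invariants are enforced", {
  expect_error(saltatory_params(duration = -1), "> 0")
  expect_error(saltatory_params(duty_cycle = 1.2), "\\[0, 1\\]")
  expect_error(saltatory_params(duty_cycle = 0.5, mean_phase_mig = 480,
                                mean_phase_stat = 100),
               "inconsistent")
  p <- saltatory_params(duty_cycle = 0.4, mean_phase_mig = 400)
  expect_equal(p$mean_phase_mig / (p$mean_phase_mig + p$mean_phase_stat),
               0.4, tolerance = 1e-9)
})

test_that("degenerate duty cycles give single-state trajectories", {
  # never migrates: all stationary, displacement is jitter only
  s0 <- simulate_trajectory(saltatory_params(duty_cycle = 0, seed = 5))
  expect_true(all(s0$truth$states == "STAT"))
  # 120 jitter steps of sd (10/3600*30) um per coord; 3x a generous
  # random-walk bound on the net displacement
  jit <- 10 / 3600 * 30
  expect_lt(net_displacement(s0$traj), 3 * jit * sqrt(2 * 120))

  # always migrates, no noise, no turning: exact straight line
  s1 <- simulate_trajectory(saltatory_params(duty_cycle = 1, v_mig = 120,
                                             v_noise = 0, turn_sd = 0,
                                             seed = 5))
  expect_true(all(s1$truth$states == "MIG"))
  expect_equal(net_displacement(s1$traj), 120, tolerance = 1e-9)
})

test_that("generators are bit-identical for a fixed seed and leave global RNG alone", {
  a <- simulate_trajectory(saltatory_params(seed = 42))
  set.seed(999)
  before <- .Random.seed
  b <- simulate_trajectory(saltatory_params(seed = 42))
  expect_identical(before, .Random.seed)
  expect_identical(a$traj$x, b$traj$x)
  expect_identical(a$truth$states, b$truth$states)
  c2 <- simulate_trajectory(saltatory_params(seed = 43))
  expect_false(identical(a$traj$x, c2$traj$x))

  sc1 <- render_puncta_stack(puncta_scene_params(seed = 7))
  sc2 <- render_puncta_stack(puncta_scene_params(seed = 7))
  expect_identical(sc1$rfp, sc2$rfp)
  expect_identical(sc1$truth, sc2$truth)
})

test_that("empirical migratory fraction converges to the duty cycle", {
  fr <- vapply(1:150, function(i) {
    simulate_trajectory(saltatory_params(duty_cycle = 0.48,
                                         seed = 2200 + i)
    )$truth$migratory_fraction
  }, numeric(1))
  expect_lt(abs(mean(fr) - 0.48), 0.02)
})

test_that("energy traces integrate the piecewise-linear model", {
  # all stationary at zero noise: pinned at r0
  ep0 <- energy_params(noise_sd = 0, seed = 1)
  sim0 <- simulate_energy_trace(rep("STAT", 20), ep0)
  expect_equal(sim0$truth$r_clean, rep(1, 21))
  expect_equal(sim0$trace$num / sim0$trace$den, rep(1, 21))

  # single migratory stretch, no clipping: final ratio = r0 - d * T
  ep <- energy_params(drop_rate = 2e-5, noise_sd = 0, seed = 1)
  simm <- simulate_energy_trace(rep("MIG", 40), ep, frame_interval = 30)
  expect_equal(simm$truth$r_clean[41], 1 - 2e-5 * 1200, tolerance = 1e-12)

  # clipping at the floor
  epf <- energy_params(drop_rate = 1e-3, r_floor = 0.9, noise_sd = 0,
                       seed = 1)
  simf <- simulate_energy_trace(rep("MIG", 30), epf)
  expect_gte(min(simf$truth$r_clean), 0.9)

  expect_error(simulate_energy_trace(character(0), ep0), "empty")
  expect_error(simulate_energy_trace(rep("BAD", 3), ep0), "MIG")
})

test_that("puncta scenes respect their constraints and export faithful truth", {
  # empty scene: pure background, nothing detectable
  sc0 <- render_puncta_stack(puncta_scene_params(n_puncta = 0, seed = 3))
  expect_equal(nrow(sc0$truth), 0L)
  expect_equal(nrow(detect_puncta(sc0$rfp, psf_sigma = 1.5)), 0L)

  # frac_dual = 1: every punctum dual-labelled
  sc1 <- render_puncta_stack(puncta_scene_params(n_puncta = 40,
                                                 frac_dual = 1, seed = 3))
  expect_true(all(sc1$truth$dual))

  # minimum separation honoured
  sc <- render_puncta_stack(puncta_scene_params(n_puncta = 60, seed = 9))
  d <- as.matrix(dist(cbind(sc$truth$y, sc$truth$x)))
  diag(d) <- Inf
  expect_gte(min(d), 4 * 1.5)

  # impossible density errors out after bounded retries
  expect_error(render_puncta_stack(
    puncta_scene_params(image_shape = c(32L, 32L), n_puncta = 500,
                        seed = 1)), "density")
})

test_that("true dual fractions are binomial around frac_dual across scenes", {
  n_scene <- 20
  tot <- dual <- 0
  for (i in 1:n_scene) {
    sc <- render_puncta_stack(puncta_scene_params(n_puncta = 100,
                                                  frac_dual = 0.355,
                                                  seed = 400 + i))
    tot <- tot + nrow(sc$truth)
    dual <- dual + sum(sc$truth$dual)
  }
  p_hat <- dual / tot
  expect_lt(abs(p_hat - 0.355), 1.96 * sqrt(0.355 * 0.645 / tot))
})

test_that("phase-coupled puncta counts carry the programmed densities", {
  states <- rep(c("STAT", "MIG"), each = 30)
  sim <- simulate_puncta_counts(states, density_stat = 0.5,
                                rel_density_mig = 0.66, area_um2 = 120,
                                seed = 11)
  expect_equal(sim$truth$density_mig, 0.33)
  expect_equal(nrow(sim$counts), 61L)
  # Poisson means recovered within sampling error on a long movie
  sim2 <- simulate_puncta_counts(rep("STAT", 2000), density_stat = 0.5,
                                 area_um2 = 120, seed = 2)
  expect_lt(abs(mean(sim2$counts$n_puncta) - 60), 3 * sqrt(60 / 2000))
})

test_that("process images place the programmed intensities along the tube", {
  # single bin, no noise: tube pixels equal mean + background
  r1 <- render_process_image(bin_means = 50, soma_mean = 80,
                             background = 7, noise_sd = 0)
  tube_vals <- setdiff(unique(as.vector(r1$image)), c(7, 87))
  expect_equal(tube_vals, 57)

  # two-bin round trip through the profiles module, exact
  r2 <- render_process_image(bin_means = c(30, 60), soma_mean = 50,
                             noise_sd = 0)
  pr <- profile_along_process(r2$image, r2$soma_mask, r2$path)
  expect_equal(pr$bin_means, c(30, 60))
  expect_equal(pr$soma_mean, 50)

  expect_error(render_process_image(bin_means = numeric(0), soma_mean = 1),
               "at least one bin")
})

test_that("noisy process renders recover the programmed gradient within Monte-Carlo error", {
  truth <- c(58.43, 40, 58.3)
  rec <- t(vapply(1:20, function(i) {
    r <- render_process_image(bin_means = truth, soma_mean = 47.7,
                              noise_sd = 5, seed = 500 + i)
    profile_along_process(r$image, r$soma_mask, r$path)$bin_means
  }, numeric(3)))
  for (b in 1:3) {
    sem <- sd(rec[, b]) / sqrt(nrow(rec))
    expect_lt(abs(mean(rec[, b]) - truth[b]), 3 * sem)
  }
})
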