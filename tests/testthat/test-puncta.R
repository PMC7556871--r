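gauss_spot <- function(ny, nx, y0, x0, amp, sigma, background = 0) {
  outer(seq_len(ny), seq_len(nx), function(y, x) {
    background + amp * exp(-((y - y0)^2 + (x - x0)^2) / (2 * sigma^2))
  })
}

test_that("detection returns nothing on blank frames and finds single spots", {
  expect_equal(nrow(detect_puncta(matrix(100, 64, 64), psf_sigma = 1.5)), 0L)

  img <- gauss_spot(64, 64, 30.5, 41.5, amp = 100, sigma = 1.5,
                    background = 10)
  set.seed(2)
  img <- img + matrix(rnorm(64 * 64, 0, 10), 64, 64)  # SNR 10
  det <- detect_puncta(img, psf_sigma = 1.5)
  expect_equal(nrow(det), 1L)
  expect_lt(sqrt((det$y - 30.5)^2 + (det$x - 41.5)^2), 1)

  expect_error(detect_puncta(matrix(0, 10, 10), psf_sigma = 5), "too large")
})

test_that("every synthetic punctum is found exactly once at zero noise", {
  # near-noiseless scene: tiny read noise, very high SNR
  sc <- render_puncta_stack(puncta_scene_params(n_puncta = 50,
                                                noise_sd = 1,
                                                peak_snr = 50, seed = 12))
  det <- detect_puncta(sc$rfp, psf_sigma = 1.5)
  m <- match_puncta(det, sc$truth, radius = 2)
  expect_equal(nrow(det), nrow(sc$truth))
  expect_equal(nrow(m$matches), nrow(sc$truth))
  expect_equal(m$f1, 1)
  expect_false(any(duplicated(m$matches$det)))
  expect_false(any(duplicated(m$matches$truth)))
})

test_that("secondary-channel classification behaves at its extremes", {
  sc <- render_puncta_stack(puncta_scene_params(n_puncta = 30, seed = 5))
  det <- detect_puncta(sc$rfp, psf_sigma = 1.5)

  # all-zero secondary channel: nothing labelled
  det0 <- classify_secondary(det, matrix(0, nrow(sc$gfp), ncol(sc$gfp)))
  expect_false(any(det0$gfp))

  # secondary = detection channel: everything labelled
  det1 <- classify_secondary(det, sc$rfp)
  expect_true(all(det1$gfp))

  expect_error(classify_secondary(det, "not a matrix"), "matrix")
})

test_that("autophagosome percentages follow the label counts", {
  p <- data.frame(id = 1:4, y = 1:4, x = 1:4,
                  gfp = c(TRUE, TRUE, FALSE, FALSE))
  class(p) <- c("puncta", "data.frame")
  expect_equal(percent_autophagosome(p), 50)
  p$gfp <- TRUE
  expect_equal(percent_autophagosome(p), 100)
  empty <- p[0, ]
  expect_warning(out <- percent_autophagosome(empty), "undefined")
  expect_true(is.na(out))
  p2 <- p
  p2$gfp <- NULL
  expect_error(percent_autophagosome(p2), "classify_secondary")
})

test_that("classification respects global intensity scaling", {
  sc <- render_puncta_stack(puncta_scene_params(n_puncta = 40,
                                                frac_dual = 0.5, seed = 19))
  det <- detect_puncta(sc$rfp, psf_sigma = 1.5)
  lab1 <- classify_secondary(det, sc$gfp)$gfp
  lab2 <- classify_secondary(det, sc$gfp * 7.3)$gfp
  expect_equal(lab1, lab2)
  expect_equal(percent_autophagosome(classify_secondary(det, sc$gfp)),
               percent_autophagosome(classify_secondary(det, sc$gfp * 7.3)))
})

test_that("estimated dual fractions sit inside the binomial confidence band", {
  tot <- pos <- 0
  for (i in 1:10) {
    sc <- render_puncta_stack(puncta_scene_params(n_puncta = 120,
                                                  frac_dual = 0.355,
                                                  image_shape = c(160L, 160L),
                                                  seed = 700 + i))
    det <- classify_secondary(detect_puncta(sc$rfp, psf_sigma = 1.5),
                              sc$gfp)
    tot <- tot + nrow(det)
    pos <- pos + sum(det$gfp)
  }
  expect_lt(abs(pos / tot - 0.355), 1.96 * sqrt(0.355 * 0.645 / tot))
})

test_that("phase densities normalise to the first stationary phase", {
  seg <- data.frame(state = c("STAT", "MIG", "STAT"),
                    t_start = c(0, 300, 600), t_end = c(300, 600, 900))
  frames <- data.frame(t = seq(0, 900, by = 30))

  # constant density everywhere: all phases at 100
  cnt <- data.frame(t = frames$t, n_puncta = 60, area_um2 = 120)
  pd <- phase_density(cnt, seg)
  expect_equal(pd$density_norm_pct, c(100, 100, 100))
  expect_equal(pd$density_norm_pct[which(seg$state == "STAT")[1L]], 100)

  # programmed 66% migratory contrast recovered exactly on clean counts
  cnt2 <- cnt
  mig_sel <- cnt2$t >= 300 & cnt2$t < 600
  cnt2$n_puncta[mig_sel] <- 39.6
  pd2 <- phase_density(cnt2, seg)
  expect_equal(pd2$density_norm_pct[2L], 66)

  # 3-point sampling equals brute-force all-frame mean on constant scenes
  all_frames <- mean(cnt$n_puncta / cnt$area_um2)
  expect_equal(pd$density[1L], all_frames)

  # short phases use what they have and get flagged
  seg_s <- data.frame(state = c("STAT", "MIG"), t_start = c(0, 60),
                      t_end = c(60, 900))
  cnt_s <- data.frame(t = seq(0, 900, by = 30), n_puncta = 60,
                      area_um2 = 120)
  pd_s <- phase_density(cnt_s, seg_s)
  expect_true(pd_s$flagged[1L])
  expect_false(pd_s$flagged[2L])

  seg_m <- data.frame(state = "MIG", t_start = 0, t_end = 900)
  expect_error(phase_density(cnt, seg_m), "no stationary")
})

test_that("kymographs turn static spots into rows and moving spots into slopes", {
  ny <- 40; nx <- 120
  path <- cbind(x = c(10, 110), y = c(20, 20))
  nt <- 20

  # static spot: same arc position lights up in every column
  stk <- array(0, c(nt, ny, nx))
  for (i in seq_len(nt)) stk[i, , ] <- gauss_spot(ny, nx, 20, 60, 100, 1.5)
  ky <- kymograph(stk, path)
  peaks <- apply(ky, 2, which.max)
  expect_equal(length(unique(peaks)), 1L)
  expect_equal(unique(peaks), 51L)  # arc 50 px from path start

  # spot moving at 2 px/frame: straight line with slope 2
  stk2 <- array(0, c(nt, ny, nx))
  for (i in seq_len(nt)) {
    stk2[i, , ] <- gauss_spot(ny, nx, 20, 20 + 2 * (i - 1), 100, 1.5)
  }
  ky2 <- kymograph(stk2, path)
  peaks2 <- apply(ky2, 2, which.max)
  fit <- coef(lm(peaks2 ~ seq_len(nt)))
  expect_equal(unname(fit[2L]), 2, tolerance = 0.05)

  expect_error(kymograph(stk, path[1, , drop = FALSE]), "degenerate")
  expect_error(kymograph(stk[1, , ], path), "T x Y x X")
})

test_that("bidirectional synthetic puncta give kymograph slopes of both signs", {
  ny <- 40; nx <- 120; nt <- 12
  path <- cbind(x = c(10, 110), y = c(20, 20))
  stk <- array(0, c(nt, ny, nx))
  for (i in seq_len(nt)) {
    stk[i, , ] <- gauss_spot(ny, nx, 20, 20 + 3 * (i - 1), 100, 1.5) +
      gauss_spot(ny, nx, 20, 100 - 3 * (i - 1), 100, 1.5)
  }
  ky <- kymograph(stk, path)
  # track each spot's ridge: forward spot starts near arc 10, backward
  # near arc 90
  fwd <- vapply(seq_len(nt), function(i) {
    which.max(ky[1:50, i])
  }, integer(1))
  bwd <- vapply(seq_len(nt), function(i) {
    50 + which.max(ky[51:101, i])
  }, numeric(1))
  expect_gt(coef(lm(fwd ~ seq_len(nt)))[2L], 2)
  expect_lt(coef(lm(bwd ~ seq_len(nt)))[2L], -2)
})
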