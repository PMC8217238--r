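px <- 0.1067
sig_px <- 0.139 / px

test_that("detection handles trivial inputs", {
  expect_identical(nrow(detect_particles(matrix(0, 64, 64))), 0L)
  expect_error(detect_particles(matrix(0, 5, 5), box = 9), "smaller")
  expect_error(detect_particles(matrix(0, 64, 64), box = 8), "odd")
  # a single bright noiseless spot yields exactly one candidate at the peak
  e <- data.frame(frame = 0L, x_um = 12 * px, y_um = 9 * px)
  img <- render_movie(e, fov = c(3, 3), n_frames = 1, background = 0,
                      poisson = FALSE)$A$pixels[1, , ]
  cand <- detect_particles(img, 1e-6, 9, psf_sigma_px = sig_px)
  expect_identical(nrow(cand), 1L)
  expect_identical(c(cand$row, cand$col),
                   as.vector(which(img == max(img), arr.ind = TRUE)[1, ]))
})

test_that("detection false-positive rate is calibrated on pure noise", {
  # marginal test level is Student-t exact, so the empirical candidate
  # count must stay below the nominal Poisson bound for both rates
  for (alpha in c(1e-3, 1e-6)) {
    set.seed(11)
    count <- 0; n_tests <- 0
    for (f in 1:20) {
      img <- matrix(stats::rnorm(256 * 256, 100, 10), 256, 256)
      count <- count + nrow(detect_particles(img, alpha, box = 9,
                                             psf_sigma_px = sig_px))
      n_tests <- n_tests + (256 - 8)^2
    }
    mu <- n_tests * alpha
    expect_lte(count, mu + 3 * sqrt(mu) + 1)
  }
})

test_that("Monte-Carlo threshold calibration agrees with the analytic null", {
  thr <- calibrate_detection_threshold(alpha_det = 1e-2, box = 9,
                                       psf_sigma_px = sig_px,
                                       n_sim = 5e4, seed = 2)
  expect_equal(thr, stats::qt(0.99, 79), tolerance = 0.05)
  expect_error(calibrate_detection_threshold(1e-3, n_sim = 10), "n_sim")
})

test_that("localization recovers sub-pixel positions exactly without noise", {
  offs <- expand.grid(dx = c(-0.3, 0, 0.25), dy = c(-0.2, 0, 0.4))
  for (k in seq_len(nrow(offs))) {
    x0 <- (14 + offs$dx[k]) * px
    y0 <- (11 + offs$dy[k]) * px
    e <- data.frame(frame = 0L, x_um = x0, y_um = y0)
    img <- render_movie(e, fov = c(3, 3), n_frames = 1, background = 2,
                        poisson = FALSE)$A$pixels[1, , ]
    cand <- detect_particles(img, 1e-4, 9, psf_sigma_px = sig_px)
    loc <- localize(img, cand[1, , drop = FALSE], psf_sigma_px = sig_px,
                    pixel_size = px)
    expect_lt(abs(loc$x_um - x0) / px, 1e-3)
    expect_lt(abs(loc$y_um - y0) / px, 1e-3)
  }
})

test_that("localization is unbiased and its precision estimate is consistent", {
  e <- data.frame(frame = 0L, x_um = 12.4 * px, y_um = 9.7 * px)
  errs_x <- c(); precs <- c()
  for (i in 1:250) {
    img <- render_movie(e, fov = c(3, 3), n_frames = 1, background = 10,
                        poisson = TRUE, seed = 1000 + i)$A$pixels[1, , ]
    cand <- detect_particles(img, 1e-4, 9, psf_sigma_px = sig_px)
    if (nrow(cand) == 0) next
    loc <- localize(img, cand[1, , drop = FALSE], psf_sigma_px = sig_px,
                    pixel_size = px)
    if (nrow(loc) == 0) next
    errs_x <- c(errs_x, loc$x_um - e$x_um)
    precs <- c(precs, loc$precision_um)
  }
  expect_gt(length(errs_x), 200)
  emp_sd <- stats::sd(errs_x)
  expect_lt(abs(mean(errs_x)), emp_sd / sqrt(length(errs_x)) * 3)
  expect_lt(abs(mean(precs) - emp_sd) / emp_sd, 0.2)
})

test_that("flat candidate patches are dropped, not localized", {
  img <- matrix(5, 31, 31)
  cand <- data.frame(row = 15, col = 15, statistic = 10)
  loc <- localize(img, cand, psf_sigma_px = sig_px, pixel_size = px)
  expect_identical(nrow(loc), 0L)
  expect_identical(attr(loc, "n_dropped"), 1L)
})

test_that("super-resolution rendering conserves localization mass", {
  one <- data.frame(frame = 0L, x_um = 5, y_um = 5, precision_um = 0.02)
  img <- render_smlm_image(one, fov = c(10, 10), upsampling = 10)
  expect_equal(sum(img), 1, tolerance = 1e-9)
  empty <- one[0, ]
  expect_true(all(render_smlm_image(empty, fov = c(10, 10)) == 0))
  # two emitters 200 nm apart with 20 nm blur are resolved at 10x grid
  two <- data.frame(frame = c(0L, 0L), x_um = c(5, 5.2), y_um = c(5, 5),
                    precision_um = 0.02)
  many <- two[rep(1:2, each = 200), ]
  img2 <- render_smlm_image(many, fov = c(10, 10), upsampling = 10)
  expect_equal(sum(img2), 400, tolerance = 1e-6)
  mid_row <- img2[round(5 / (px / 10)) + 1, ]
  peaks <- which(diff(sign(diff(mid_row))) == -2) + 1
  expect_gte(length(peaks), 2)
})

test_that("density QC applies the per-channel selection rule", {
  mk <- function(per_frame, n_frames = 10)
    data.frame(frame = rep(seq_len(n_frames) - 1, each = per_frame),
               channel = "A")
  expect_true(density_qc(mk(50), area = 100, n_frames = 10)$accept)
  expect_false(density_qc(mk(150), area = 100, n_frames = 10)$accept)
  expect_error(density_qc(mk(10), area = 0, n_frames = 10), "area")
  # simulated scenario at density 0.8 measures ~0.8 per um^2
  sc <- free_scenario(n_frames = 50, fov = c(20, 20), density = 0.8, seed = 8)
  sim <- simulate_trajectories(sc)
  qc <- density_qc(sim$localizations, area = 400, n_frames = 50)
  expect_lt(abs(qc$density[["A"]] - 0.8), 3 * sqrt(320) / 400)
  expect_true(qc$accept)
})
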