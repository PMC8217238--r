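test_that("free Brownian steps have the closed-form variance", {
  dt <- 0.032
  sc <- free_scenario(n_frames = 101, fov = c(60, 60), density = 200 / 3600,
                      seed = 1, eps = 0)
  sim <- simulate_trajectories(sc)
  pos <- sim$truth$positions
  dx <- unlist(lapply(split(pos, pos$complex_id), function(p) {
    p <- p[order(p$frame), ]
    diff(p$x_um)
  }), use.names = FALSE)
  expect_gt(length(dx), 1e4)
  v_expect <- 2 * 0.19 * dt                 # per-axis step variance
  se <- v_expect * sqrt(2 / length(dx))     # sd of a variance estimate
  expect_lt(abs(stats::var(dx) - v_expect), 3 * se)
  # mean squared 2D single-frame displacement = 4 D dt
  dy <- unlist(lapply(split(pos, pos$complex_id), function(p)
    diff(p$y_um[order(p$frame)])), use.names = FALSE)
  msd1 <- mean(dx^2 + dy^2)
  expect_lt(abs(msd1 - 4 * 0.19 * dt), 3 * 4 * 0.19 * dt * sqrt(2 / length(dx)))
})

test_that("trapping kinetics follow the two-state chain", {
  # no arrest prob -> no arrested frames
  sc0 <- free_scenario(n_frames = 50, fov = c(20, 20), density = 0.1,
                       seed = 2, trap = trap_model(0, 0.3))
  expect_identical(sum(simulate_trajectories(sc0)$truth$positions$state), 0L)

  # stationary occupancy p_arrest / (p_arrest + p_release) = 0.25
  sc <- free_scenario(n_frames = 2000, fov = c(20, 20), density = 0.125,
                      seed = 3, trap = trap_model(0.1, 0.3))
  pos <- simulate_trajectories(sc)$truth$positions
  per_chain <- tapply(pos$state, pos$complex_id, mean)
  se <- stats::sd(per_chain) / sqrt(length(per_chain))
  expect_lt(abs(mean(per_chain) - 0.25), 3 * se)

  # arrested positions stay inside their domain disc
  sct <- free_scenario(n_frames = 500, fov = c(20, 20), density = 0.05,
                       seed = 4, trap = trap_model(0.05, 0.02, 0.035, 0.01))
  post <- simulate_trajectories(sct)$truth$positions
  for (cx in split(post, post$complex_id)) {
    cx <- cx[order(cx$frame), ]
    for (seg in cut_segments(cx, cx$state == 1)) {
      if (nrow(seg) < 2) next
      # all arrested positions lie within one domain-diameter of the first
      d <- sqrt((seg$x_um - seg$x_um[1])^2 + (seg$y_um - seg$y_um[1])^2)
      expect_lte(max(d), 0.035)
    }
  }
})

test_that("oligomer labeling matches the brute-force enumeration oracle", {
  for (n in 1:6) {
    for (p in c(0.05, 0.1, 0.5)) {
      exact <- enumerate_dual_fraction(n, p, 0.5)
      expect_equal(dual_labeled_fraction(n, p, 0.5), exact, tolerance = 1e-12)
    }
  }
  # spec'd closed-form case n = 4, p = 0.1
  expect_equal(dual_labeled_fraction(4, 0.1, 0.5),
               1 - 2 * (1 - 0.05)^4 + (1 - 0.1)^4, tolerance = 1e-12)
  # single subunit can never be dual-labeled
  expect_identical(simulate_oligomer_labeling(1, 0.9, 0.5, 500)$dual_fraction, 0)
  # n = 2, full labeling, even split -> 1/2
  expect_equal(dual_labeled_fraction(2, 1, 0.5), 0.5)
  # stochastic realisation agrees within 3 binomial SEs
  nsim <- 20000
  sim <- simulate_oligomer_labeling(4, 0.1, 0.5, nsim, seed = 5)
  exact <- enumerate_dual_fraction(4, 0.1, 0.5)
  expect_lt(abs(sim$dual_fraction - exact),
            3 * sqrt(exact * (1 - exact) / nsim))
  # monotonicity of the dual-labeled fraction in complex size
  f <- vapply(1:6, dual_labeled_fraction, numeric(1), p_label = 0.1)
  expect_true(all(diff(f) > 0))
})

test_that("movie rendering conserves photons and is seed-reproducible", {
  none <- data.frame(frame = integer(0), x_um = numeric(0), y_um = numeric(0))
  mv0 <- render_movie(none, fov = c(2, 2), n_frames = 2, background = 0,
                      poisson = FALSE)
  expect_true(all(mv0$A$pixels == 0))
  e <- data.frame(frame = 0L, x_um = 1.0, y_um = 0.9)
  mv <- render_movie(e, fov = c(2, 2), n_frames = 1, background = 0,
                     poisson = FALSE, photons_per_spot = 500)
  expect_equal(sum(mv$A$pixels), 500, tolerance = 1e-6)
  mv1 <- render_movie(e, fov = c(2, 2), n_frames = 1, seed = 7)
  mv2 <- render_movie(e, fov = c(2, 2), n_frames = 1, seed = 7)
  expect_identical(mv1$A$pixels, mv2$A$pixels)
  expect_error(render_movie(e, fov = c(2, 2), n_frames = 1,
                            photons_per_spot = -5), "photons")
})

test_that("trajectory generator is bit-reproducible and validates input", {
  sc <- free_scenario(n_frames = 20, fov = c(10, 10), density = 0.2, seed = 6)
  expect_identical(simulate_trajectories(sc), simulate_trajectories(sc))
  expect_error(trap_model(p_arrest = 1.5), "probabilities")
  expect_error(sim_scenario(d_free = -1), "d_free")
  expect_error(sim_scenario(p_label = 2), "p_label")
  expect_error(sim_scenario(density = 100, fov = c(100, 100), p_label = 1,
                            max_particles = 500), "cap")
  expect_error(sim_scenario(n_frames = 1), "n_frames")
})

test_that("FRAP simulator produces the stated ideal curves", {
  # immobile pool only: flat post-bleach series
  s <- simulate_frap(0, recovery_rate = 0.2, bleach_depth = 0.8,
                     n_pre = 5, n_post = 50, dt = 0.5)
  post <- s$bleach[-(1:5)]
  expect_equal(max(abs(post - 0.2)), 0, tolerance = 1e-12)
  # no acquisition bleaching: control ROI flat
  expect_equal(max(abs(s$control - 1)), 0, tolerance = 1e-12)
  s2 <- simulate_frap(0.5, acquisition_bleach_rate = 0.01, n_pre = 5,
                      n_post = 50, dt = 0.5)
  expect_true(all(diff(s2$control) < 0))
  expect_error(simulate_frap(0.5, n_pre = 0), "n_pre")
  expect_error(simulate_frap(1.2), "mobile_fraction")
})
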