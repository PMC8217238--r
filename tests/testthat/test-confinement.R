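dt <- 0.032

test_that("confinement threshold calibration behaves like a null quantile", {
  # alpha = 0.5 reproduces the median of the null L distribution
  L_med <- calibrate_confinement_threshold(alpha_conf = 0.5, n_sim = 2e4,
                                           seed = 51)
  Lnull <- withr::with_seed(52, sptlock:::null_window_L(2e4, 0.19, 10, dt, 0.02))
  expect_lt(abs(L_med - stats::median(Lnull)), 0.05)
  # threshold grows as alpha shrinks
  Ls <- vapply(c(0.05, 1e-2, 1e-3),
               function(a) calibrate_confinement_threshold(
                 alpha_conf = a, n_sim = 2e5, seed = 53), numeric(1))
  expect_true(all(diff(Ls) > 0))
  # doubling n_sim moves the threshold by < 5%
  L1 <- calibrate_confinement_threshold(alpha_conf = 1e-3, n_sim = 2e5, seed = 54)
  L2 <- calibrate_confinement_threshold(alpha_conf = 1e-3, n_sim = 4e5, seed = 55)
  expect_lt(abs(L2 - L1) / L1, 0.05)
  expect_error(calibrate_confinement_threshold(alpha_conf = 1e-3, n_sim = 100),
               "n_sim")
})

test_that("static trajectories score far above threshold, free ones below", {
  L_star <- calibrate_confinement_threshold(alpha_conf = 1e-3, n_sim = 2e5,
                                            seed = 56)
  set.seed(57)
  static <- data.frame(frame = 0:119, x_um = 5 + rnorm(120, 0, 0.02),
                       y_um = 5 + rnorm(120, 0, 0.02))
  prof <- confinement_index(static)
  expect_true(all(prof$L[!is.na(prof$L)] > L_star))
  st <- segment_states(prof, L_star)
  expect_true(all(st$state == 1L))
  # all-zero profile segments to fully mobile
  flat <- data.frame(frame = 0:119, L = c(rep(NA, 4), rep(0, 111), rep(NA, 5)))
  expect_true(all(segment_states(flat, L_star)$state == 0L))
  # short trajectories are rejected
  expect_error(confinement_index(static[1:50, ]), "exceed")
})

test_that("segmentation recovers simulated two-state trajectories", {
  L_star <- calibrate_confinement_threshold(alpha_conf = 1e-3, n_sim = 2e5,
                                            seed = 58)
  sc <- free_scenario(n_frames = 600, fov = c(30, 30), density = 30 / 900,
                      seed = 59, trap = trap_model(0.02, 0.05, 0.035, 0.005))
  sim <- simulate_trajectories(sc)
  locs <- sim$localizations
  pos <- sim$truth$positions
  acc <- c()
  for (pid in unique(locs$particle_id)) {
    li <- locs[locs$particle_id == pid, ]
    prof <- confinement_index(li)
    st <- segment_states(prof, L_star)
    truth <- pos$state[pos$complex_id == li$complex_id[1]]
    acc <- c(acc, mean(st$state == truth))
  }
  expect_gte(mean(acc), 0.90)
})

test_that("transition estimates are exact counts and recover chain rates", {
  tr <- estimate_transitions(c(0, 0, 1, 1, 1, 0))
  expect_equal(tr$p_arrest, 0.5)
  expect_equal(tr$p_release, 1 / 3)
  # never-arrested input: release probability undefined
  tr0 <- estimate_transitions(list(rep(0, 50), rep(0, 30)))
  expect_equal(tr0$p_arrest, 0)
  expect_true(is.na(tr0$p_release))
  # invariance to trajectory order (no cross-boundary transitions)
  seqs <- list(c(0, 1, 1, 0), c(1, 1, 0, 0), c(0, 0, 0, 1))
  expect_identical(estimate_transitions(seqs)$counts,
                   estimate_transitions(rev(seqs))$counts)
  # simulated chains: estimates within 3 binomial SEs
  set.seed(60)
  p01 <- 0.02; p10 <- 0.05
  chains <- lapply(1:50, function(i) {
    s <- integer(400); s[1] <- rbinom(1, 1, p01 / (p01 + p10))
    for (t in 2:400)
      s[t] <- if (s[t - 1] == 0) rbinom(1, 1, p01) else 1 - rbinom(1, 1, p10)
    s
  })
  est <- estimate_transitions(chains)
  n0 <- sum(est$counts[1, ]); n1 <- sum(est$counts[2, ])
  expect_lt(abs(est$p_arrest - p01), 3 * sqrt(p01 * (1 - p01) / n0))
  expect_lt(abs(est$p_release - p10), 3 * sqrt(p10 * (1 - p10) / n1))
})

test_that("domain-size estimator is unbiased on uniform-disc data", {
  # analytic identity: mean squared pair displacement in a disc = R^2
  set.seed(61)
  pts <- uniform_disc(20000, diameter = 0.035)
  est <- estimate_domain_size(list(pts), epsilon = 0, min_lag = 6,
                              max_lag = 30)
  expect_lt(abs(est$diameter_um - 0.035) / 0.035, 0.03)
  # pure localization noise: plateau ~ 4 eps^2, diameter ~ 0
  noise <- data.frame(x_um = rnorm(20000, 0, 0.02),
                      y_um = rnorm(20000, 0, 0.02))
  est2 <- estimate_domain_size(list(noise), epsilon = 0.02)
  expect_true(est2$clipped || est2$diameter_um < 0.012)
  # insufficient data: missing value
  est3 <- estimate_domain_size(list(), epsilon = 0.02)
  expect_true(is.na(est3$diameter_um))
})

test_that("end-to-end confinement analysis flags trapped trajectories", {
  sc <- free_scenario(n_frames = 300, fov = c(30, 30), density = 20 / 900,
                      seed = 62, trap = trap_model(0.02, 0.03, 0.035, 0.005))
  sim <- simulate_trajectories(sc)
  locs <- sim$localizations
  locs$trajectory_id <- locs$particle_id
  res <- analyze_confinement(locs, seed = 63)
  had_arrest <- tapply(truth_states(sim), locs$particle_id,
                       function(s) any(s == 1))
  expect_gt(res$confined_fraction, 0)
  expect_lt(abs(res$confined_fraction - mean(had_arrest)), 0.25)
  expect_true(res$transitions$p_arrest > 0)
})
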