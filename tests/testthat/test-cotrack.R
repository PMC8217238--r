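dt <- 0.032

test_that("bead calibration recovers affine channel transforms", {
  set.seed(41)
  bb <- data.frame(x_um = runif(10, 0, 50), y_um = runif(10, 0, 50))
  # identity
  tf0 <- calibrate_transform(bb, bb)
  expect_equal(tf0$matrix, cbind(diag(2), c(0, 0)), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_lt(tf0$rmse_um, 1e-12)
  # pure translation recovered exactly
  ba <- data.frame(x_um = bb$x_um + 0.5, y_um = bb$y_um - 0.2)
  tf1 <- calibrate_transform(ba, bb)
  expect_equal(tf1$matrix[, 3], c(0.5, -0.2), tolerance = 1e-9,
               ignore_attr = TRUE)
  p <- apply_transform(tf1, 3, 7)
  expect_equal(c(p$x, p$y), c(3.5, 6.8), tolerance = 1e-9)
  # small rotation + scale with 5 nm bead noise
  th <- 0.002; s <- 1.01
  M <- rbind(c(s * cos(th), -s * sin(th), 0.4),
             c(s * sin(th), s * cos(th), -0.1))
  ba2 <- data.frame(
    x_um = M[1, 1] * bb$x_um + M[1, 2] * bb$y_um + M[1, 3] + rnorm(10, 0, 0.005),
    y_um = M[2, 1] * bb$x_um + M[2, 2] * bb$y_um + M[2, 3] + rnorm(10, 0, 0.005))
  tf2 <- calibrate_transform(ba2, bb)
  expect_lt(max(abs(tf2$matrix[, 1:2] - M[, 1:2])), 1e-3)
  expect_lt(tf2$rmse_um, 0.010)
  # degenerate inputs are rejected
  expect_error(calibrate_transform(ba[1:2, ], bb[1:2, ]), "3 bead")
  col <- data.frame(x_um = 1:5, y_um = 2 * (1:5))
  expect_error(calibrate_transform(col, col), "collinear")
})

test_that("a dual-labeled complex is co-tracked over its full span", {
  sc <- sim_scenario(d_free = 0.19, frame_interval = dt, n_frames = 100,
                     fov = c(20, 20), boundary = "reflecting", density = 0.05,
                     oligomer_size_dist = c("2" = 1), p_label = 1,
                     color_split = 0.5, loc_noise_sigma = 0.02, seed = 42)
  sim <- simulate_trajectories(sc)
  dual <- sim$truth$complexes$n_labels_a > 0 & sim$truth$complexes$n_labels_b > 0
  la <- sim$localizations[sim$localizations$channel == "A", ]
  lb <- sim$localizations[sim$localizations$channel == "B", ]
  ta <- link_trajectories(la, dt); tb <- link_trajectories(lb, dt)
  ct <- cotrack(ta, tb)
  expect_gte(nrow(ct$cotrajectories), sum(dual))
  expect_gte(sum(ct$cotrajectories$n_frames), 90 * sum(dual))
  # two particles at constant 400 nm separation never co-track
  set.seed(43)
  t1 <- data.frame(trajectory_id = 1, frame = 0:49,
                   x_um = 5 + cumsum(rnorm(50, 0, 0.05)), y_um = 5)
  t2 <- t1; t2$trajectory_id <- 2; t2$x_um <- t1$x_um + 0.4
  expect_identical(nrow(cotrack(t1, t2)$cotrajectories), 0L)
})

test_that("dual-labeled fraction matches the labeling forward model", {
  p <- 0.5
  sc <- sim_scenario(d_free = 0.19, frame_interval = dt, n_frames = 60,
                     fov = c(25, 25), boundary = "reflecting", density = 0.3,
                     oligomer_size_dist = c("2" = 1), p_label = p,
                     color_split = 0.5, loc_noise_sigma = 0.02, seed = 44)
  sim <- simulate_trajectories(sc)
  la <- sim$localizations[sim$localizations$channel == "A", ]
  lb <- sim$localizations[sim$localizations$channel == "B", ]
  ta <- link_trajectories(la, dt); tb <- link_trajectories(lb, dt)
  ct <- cotrack(ta, tb)
  # expected fraction of localizations that sit in dual-labeled dimers:
  # P(dual) complexes carry 2 of the 2p expected labels per complex
  expected <- dual_labeled_fraction(2, p, 0.5) / p
  n_cx <- nrow(sim$truth$complexes)
  se <- sqrt(expected * (1 - expected) / n_cx)
  expect_lt(abs(ct$dual_fraction - expected), 3 * se + 0.02)
  # swapping the channels leaves the fraction unchanged
  ct_swap <- cotrack(tb, ta)
  expect_equal(ct_swap$dual_fraction, ct$dual_fraction, tolerance = 1e-9)
})

test_that("empty channels produce an explicit zero-count result", {
  none <- data.frame(trajectory_id = integer(0), frame = integer(0),
                     x_um = numeric(0), y_um = numeric(0))
  some <- data.frame(trajectory_id = 1, frame = 0:20, x_um = 1, y_um = 1)
  res <- cotrack(none, some)
  expect_identical(nrow(res$cotrajectories), 0L)
  expect_identical(res$n, 21L)
  res0 <- cotrack(none, none)
  expect_true(is.na(res0$dual_fraction))
  expect_identical(res0$n, 0L)
})

test_that("co-localized immobile events require overlap and proximity", {
  ea <- data.frame(event_id = 1:2, centroid_x_um = c(1, 5),
                   centroid_y_um = c(1, 5), start_frame = c(0, 100),
                   end_frame = c(50, 130))
  eb <- data.frame(event_id = 1:2, centroid_x_um = c(1.05, 5.5),
                   centroid_y_um = c(1, 5), start_frame = c(10, 100),
                   end_frame = c(60, 130))
  ce <- cotrack_events(ea, eb)
  # event 1: within 50 nm, 41 overlapping frames -> co-classified
  # event 2: 500 nm apart -> not
  expect_identical(nrow(ce), 1L)
  expect_identical(ce$event_a, 1L)
})
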