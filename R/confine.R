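#' Confinement index along a trajectory
#'
#' For every sliding window of `window` frames, the maximal excursion
#' radius `R_w` (largest distance from the window's first position) is
#' converted into the probability `psi` that free Brownian motion with
#' diffusion coefficient `d_null` stays within `R_w` for the window
#' duration, using the Simson-Sheetz approximation
#' `log10(psi) = 0.2048 - 2.5117 * d_null * t_w / R_w^2` with
#' `t_w = (window - 1) * dt`.  The confinement index is
#' `L = -log10(psi)`, clipped at 0.  Windows interrupted by observation
#' gaps are reported as `NA`, as are the edge frames that no full window
#' covers; the profile is aligned to window centres.
#'
#' Any miscalibration of the analytic approximation is absorbed by the
#' Monte-Carlo threshold of [calibrate_confinement_threshold()], which
#' uses the identical statistic.
#'
#' @param traj data.frame of one trajectory (`frame`, `x_um`, `y_um`),
#'   longer than 100 frames.
#' @param window Window length in frames (default 10, i.e. 320 ms at
#'   32 ms/frame).
#' @param d_null Free diffusion coefficient of the null model in um^2/s
#'   (default 0.19, the unhindered monomer).
#' @param dt Frame interval in seconds.
#' @param min_traj_frames Minimum trajectory length for the analysis
#'   (default 100 frames; shorter trajectories are rejected).
#' @return data.frame `frame`, `L`.
#' @export
confinement_index <- function(traj, window = 10, d_null = 0.19,
                              dt = 0.032, min_traj_frames = 100) {
  if (d_null <= 0) stop("d_null must be > 0")
  o <- order(traj$frame)
  fr <- traj$frame[o]; x <- traj$x_um[o]; y <- traj$y_um[o]
  if (length(fr) <= min_traj_frames)
    stop(sprintf("trajectory must exceed %d frames", min_traj_frames))
  span <- max(fr) - min(fr) + 1
  if (span < window) stop("window longer than trajectory")
  f0 <- fr - fr[1]
  px <- rep(NA_real_, span); py <- px
  px[f0 + 1] <- x; py[f0 + 1] <- y
  tw <- (window - 1) * dt
  nwin <- span - window + 1
  Lwin <- rep(NA_real_, nwin)
  for (i in seq_len(nwin)) {
    xs <- px[i:(i + window - 1)]; ys <- py[i:(i + window - 1)]
    if (anyNA(xs)) next
    r2 <- max((xs - xs[1])^2 + (ys - ys[1])^2)
    Lwin[i] <- confinement_L(r2, d_null, tw)
  }
  centre <- seq_len(nwin) + floor(window / 2) - 1
  L <- rep(NA_real_, span)
  L[centre + 1] <- Lwin
  data.frame(frame = fr[1] + seq_len(span) - 1L, L = L)
}

confinement_L <- function(r2_max, d_null, tw) {
  if (r2_max <= 0) return(Inf)
  pmax(2.5117 * d_null * tw / r2_max - 0.2048, 0)
}

#' Calibrate the confinement threshold on simulated free diffusion
#'
#' Simulates `n_sim` independent windows of free Brownian motion with the
#' null diffusion coefficient and the configured localization noise,
#' computes the confinement index of each, and returns the empirical
#' `1 - alpha_conf` quantile as the threshold `L*`.  Windows of genuinely
#' free motion then exceed `L*` at the nominal false-positive rate.
#'
#' @inheritParams confinement_index
#' @param alpha_conf Nominal false-positive rate (default `1e-3`).
#' @param n_sim Number of simulated windows; at least `100 / alpha_conf`
#'   required for a stable quantile.
#' @param loc_noise_sigma Per-axis localization noise in micrometers
#'   included in the null simulation (default 0.020), so the threshold is
#'   calibrated against the same observation process as real data.
#' @param seed Integer seed; the threshold is deterministic given the
#'   seed.
#' @return Scalar threshold `L*`.
#' @export
calibrate_confinement_threshold <- function(d_null = 0.19, window = 10,
                                            dt = 0.032, alpha_conf = 1e-3,
                                            n_sim = ceiling(100 / alpha_conf),
                                            loc_noise_sigma = 0.020,
                                            seed = 1L) {
  if (n_sim < 100 / alpha_conf)
    stop(sprintf("n_sim must be >= %d for alpha_conf = %g",
                 ceiling(100 / alpha_conf), alpha_conf))
  L <- withr::with_seed(seed,
    null_window_L(n_sim, d_null, window, dt, loc_noise_sigma))
  unname(stats::quantile(L, 1 - alpha_conf, type = 8))
}

# confinement index of n independent free-motion windows (vectorised)
null_window_L <- function(n, d_null, window, dt, eps) {
  sd_step <- sqrt(2 * d_null * dt)
  dx <- matrix(stats::rnorm(n * (window - 1), 0, sd_step), n)
  dy <- matrix(stats::rnorm(n * (window - 1), 0, sd_step), n)
  X <- cbind(0, t(apply(dx, 1, cumsum)))
  Y <- cbind(0, t(apply(dy, 1, cumsum)))
  if (window == 2) { X <- cbind(0, dx); Y <- cbind(0, dy) }
  if (eps > 0) {
    X <- X + matrix(stats::rnorm(length(X), 0, eps), n)
    Y <- Y + matrix(stats::rnorm(length(Y), 0, eps), n)
  }
  r2 <- apply((X - X[, 1])^2 + (Y - Y[, 1])^2, 1, max)
  tw <- (window - 1) * dt
  pmax(2.5117 * d_null * tw / r2 - 0.2048, 0)
}

#' Segment a confinement profile into mobile/arrested states
#'
#' Frames whose window confinement index exceeds the threshold `L*` are
#' marked arrested (state 1); runs shorter than `min_arrest_frames` are
#' reverted to mobile.  Edge frames without a defined window inherit the
#' state of the nearest defined window.
#'
#' @param profile data.frame from [confinement_index()] (`frame`, `L`).
#' @param L_star Threshold from [calibrate_confinement_threshold()].
#' @param min_arrest_frames Minimum arrest duration in frames (default 10,
#'   one full window, so an arrest must be supported by at least one
#'   complete window).
#' @return data.frame `frame`, `state` (0 mobile, 1 arrested).
#' @export
segment_states <- function(profile, L_star, min_arrest_frames = 10) {
  L <- profile$L
  if (all(is.na(L))) stop("profile has no defined windows")
  st <- as.integer(L > L_star)
  # fill edge/gap NAs with the nearest defined state
  nas <- which(is.na(st))
  if (length(nas)) {
    def <- which(!is.na(st))
    nearest <- def[pmax(1, findInterval(nas, def))]
    # findInterval gives the last def <= na; compare with the next one
    nxt <- def[pmin(length(def), findInterval(nas, def) + 1)]
    closer <- ifelse(abs(nas - nearest) <= abs(nxt - nas), nearest, nxt)
    st[nas] <- st[closer]
  }
  r <- rle(st)
  short <- r$values == 1L & r$lengths < min_arrest_frames
  r$values[short] <- 0L
  data.frame(frame = profile$frame, state = inverse.rle(r))
}

#' Maximum-likelihood transition probabilities from state sequences
#'
#' Fully observed two-state Markov chain estimates pooled over
#' trajectories: `p(i -> j) = n_ij / sum_k n_ik`, where transitions are
#' never counted across trajectory boundaries.  Dwell-time summaries of
#' completed arrest episodes are also reported.
#'
#' @param states A list of integer vectors (or data.frames with a `state`
#'   column), one per trajectory, with values 0 (mobile) / 1 (arrested).
#' @return List with `p_arrest`, `p_release` (`NA` when the source state
#'   is never visited), `counts` (2 x 2 transition count matrix) and
#'   `dwell_arrest_frames` (lengths of completed arrested runs).
#' @export
estimate_transitions <- function(states) {
  if (is.data.frame(states) || is.numeric(states)) states <- list(states)
  counts <- matrix(0, 2, 2,
                   dimnames = list(c("mobile", "arrested"),
                                   c("mobile", "arrested")))
  dwell <- integer(0)
  for (s in states) {
    v <- if (is.data.frame(s)) s$state else s
    v <- as.integer(v)
    if (length(v) < 2) next
    a <- v[-length(v)]; b <- v[-1]
    counts[1, 1] <- counts[1, 1] + sum(a == 0 & b == 0)
    counts[1, 2] <- counts[1, 2] + sum(a == 0 & b == 1)
    counts[2, 1] <- counts[2, 1] + sum(a == 1 & b == 0)
    counts[2, 2] <- counts[2, 2] + sum(a == 1 & b == 1)
    r <- rle(v)
    # completed arrest episodes only (not touching either end)
    k <- which(r$values == 1L)
    k <- k[k > 1 & k < length(r$values)]
    dwell <- c(dwell, r$lengths[k])
  }
  n0 <- sum(counts[1, ]); n1 <- sum(counts[2, ])
  list(p_arrest = if (n0 > 0) counts[1, 2] / n0 else NA_real_,
       p_release = if (n1 > 0) counts[2, 1] / n1 else NA_real_,
       counts = counts,
       dwell_arrest_frames = dwell)
}

#' Estimate the trapping-domain diameter from arrested-segment MSD
#'
#' For positions uniformly distributed in a disc of radius `R`, the mean
#' squared pair displacement is exactly `R^2` (twice the mean squared
#' radius `R^2/2`); with per-axis localization noise `eps` the observed
#' MSD plateaus at `R^2 + 4 eps^2`.  The plateau is estimated as the mean
#' pooled MSD over lags beyond 5 frames and inverted to
#' `diameter = 2 * sqrt(plateau - 4 eps^2)`.  A negative radicand yields
#' a diameter of 0 with `clipped = TRUE`.
#'
#' @param segments List of data.frames (`x_um`, `y_um`, consecutive
#'   frames) of arrested periods, e.g. cut from trajectories by
#'   [segment_states()] or from simulation ground truth.
#' @param epsilon Per-axis localization precision in micrometers.
#' @param min_lag,max_lag Lag range (frames) pooled for the plateau
#'   (defaults 6 and 30).  The lower bound excludes lags still dominated
#'   by the residual in-domain diffusion; the upper bound spans several
#'   in-domain correlation times while staying below typical arrest dwell
#'   times.
#' @return List with `diameter_um`, `plateau_um2`, `n_pairs`, `clipped`;
#'   `diameter_um` is `NA` when fewer than 5 lags have pairs.
#' @export
estimate_domain_size <- function(segments, epsilon, min_lag = 6,
                                 max_lag = 30) {
  sum_d2 <- numeric(max_lag); n_d2 <- numeric(max_lag)
  for (s in segments) {
    m <- nrow(s)
    if (is.null(m) || m < 2) next
    for (k in seq_len(min(max_lag, m - 1))) {
      i <- seq_len(m - k)
      d2 <- (s$x_um[i + k] - s$x_um[i])^2 + (s$y_um[i + k] - s$y_um[i])^2
      sum_d2[k] <- sum_d2[k] + sum(d2)
      n_d2[k] <- n_d2[k] + length(d2)
    }
  }
  lags <- which(n_d2 > 0 & seq_len(max_lag) >= min_lag)
  if (!length(lags) || sum(n_d2 > 0) < 5)
    return(list(diameter_um = NA_real_, plateau_um2 = NA_real_,
                n_pairs = 0, clipped = FALSE))
  # unweighted mean of the per-lag MSDs: weighting by pair counts would
  # over-weight the shortest lags, which still carry residual in-domain
  # motion correlation
  plateau <- mean(sum_d2[lags] / n_d2[lags])
  rad2 <- plateau - 4 * epsilon^2
  clipped <- rad2 < 0
  list(diameter_um = if (clipped) 0 else 2 * sqrt(rad2),
       plateau_um2 = plateau,
       n_pairs = sum(n_d2[lags]),
       clipped = clipped)
}

#' Confinement analysis of a set of trajectories
#'
#' Runs [confinement_index()], [segment_states()] and
#' [estimate_transitions()] over all trajectories longer than
#' `min_traj_frames`, and estimates the nanodomain diameter from the
#' pooled arrested segments.
#'
#' @param locs Localization data.frame with `trajectory_id`.
#' @param L_star Threshold; computed via
#'   [calibrate_confinement_threshold()] when `NULL`.
#' @inheritParams confinement_index
#' @inheritParams calibrate_confinement_threshold
#' @param min_arrest_frames Minimum arrest duration (frames).
#' @param epsilon Localization precision used for the domain-size
#'   estimate.
#' @param seed Seed for the threshold calibration.
#' @return List with `profiles` (per-trajectory `frame`, `L`, `state`),
#'   `confined_fraction` (fraction of analyzed trajectories with at least
#'   one arrest), `transitions`, `domain` (see [estimate_domain_size()]),
#'   `L_star`, `n_trajectories`.
#' @export
analyze_confinement <- function(locs, window = 10, d_null = 0.19,
                                dt = 0.032, alpha_conf = 1e-3,
                                L_star = NULL, min_arrest_frames = 10,
                                min_traj_frames = 100,
                                epsilon = 0.020, seed = 1L) {
  if (is.null(L_star))
    L_star <- calibrate_confinement_threshold(
      d_null = d_null, window = window, dt = dt, alpha_conf = alpha_conf,
      loc_noise_sigma = epsilon, seed = seed)
  sp <- split(locs[, c("frame", "x_um", "y_um")], locs$trajectory_id)
  sp <- sp[vapply(sp, nrow, integer(1)) > min_traj_frames]
  profiles <- list(); states <- list(); segments <- list()
  has_arrest <- logical(length(sp))
  for (i in seq_along(sp)) {
    prof <- confinement_index(sp[[i]], window = window, d_null = d_null,
                              dt = dt, min_traj_frames = min_traj_frames)
    if (all(is.na(prof$L))) next  # every window interrupted by gaps
    st <- segment_states(prof, L_star, min_arrest_frames)
    profiles[[i]] <- cbind(trajectory_id = names(sp)[i], prof,
                           state = st$state)
    states[[i]] <- st$state
    has_arrest[i] <- any(st$state == 1L)
    if (has_arrest[i]) {
      tr <- sp[[i]][order(sp[[i]]$frame), ]
      stf <- st$state[match(tr$frame, st$frame)]
      r <- rle(stf)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
      for (k in which(r$values == 1L))
        segments[[length(segments) + 1]] <- tr[starts[k]:ends[k], ]
    }
  }
  list(profiles = if (length(profiles)) do.call(rbind, profiles) else NULL,
       confined_fraction = if (length(sp)) mean(has_arrest) else NA_real_,
       transitions = estimate_transitions(states),
       domain = estimate_domain_size(segments, epsilon),
       L_star = L_star,
       n_trajectories = length(sp))
}
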