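#' Link mobile localizations into trajectories
#'
#' Frame-to-frame linking by globally optimal assignment (minimum total
#' squared displacement, solved as a rectangular linear assignment problem
#' per frame) subject to a per-trajectory adaptive gate equal to
#' `gate_factor` times the trajectory's running step standard deviation
#' (initialized from the expected free-diffusion step for `d_init`).
#' Unmatched trajectory ends persist for up to `max_gap` frames before
#' closing, so observation gaps of at most `max_gap` consecutive frames are
#' bridged; each localization is used at most once, and localizations not
#' linked to any existing trajectory start new ones.
#'
#' @param locs Localization data.frame (`frame` 0-based, `x_um`, `y_um`);
#'   immobile members should have been removed (see [find_immobile()]).
#' @param frame_interval Frame interval in seconds.
#' @param max_gap Maximum bridged gap in frames (default 3).
#' @param gate_factor Gate width in units of the running step sd
#'   (default 3).
#' @param d_init Diffusion coefficient (um^2/s) used for the initial gate;
#'   a generous upper bound (default 0.5).
#' @return The input data.frame with a `trajectory_id` column, ordered by
#'   trajectory and frame.
#' @export
link_trajectories <- function(locs, frame_interval = 0.032, max_gap = 3,
                              gate_factor = 3, d_init = 0.5) {
  n <- nrow(locs)
  if (n == 0) {
    locs$trajectory_id <- integer(0)
    return(locs)
  }
  ord <- order(locs$frame)
  x <- locs$x_um[ord]; y <- locs$y_um[ord]; fr <- locs$frame[ord]
  idx_by_frame <- split(seq_len(n), fr)
  frames <- as.integer(names(idx_by_frame))

  s2_init <- 4 * d_init * frame_interval   # E|step|^2 for the prior
  w0 <- 4                                   # prior weight (pseudo-steps)

  cap <- 1024L
  tr_x <- numeric(cap); tr_y <- numeric(cap)
  tr_last <- integer(cap); tr_ssq <- numeric(cap); tr_nstep <- numeric(cap)
  tr_open <- logical(cap)
  n_tr <- 0L
  traj_of <- integer(n)

  grow <- function() {
    cap2 <- cap * 2L
    length(tr_x) <<- cap2; length(tr_y) <<- cap2
    length(tr_last) <<- cap2; length(tr_ssq) <<- cap2
    length(tr_nstep) <<- cap2
    tr_open <<- c(tr_open, logical(cap))
    cap <<- cap2
  }
  new_traj <- function(li, f) {
    n_tr <<- n_tr + 1L
    if (n_tr > cap) grow()
    tr_x[n_tr] <<- x[li]; tr_y[n_tr] <<- y[li]
    tr_last[n_tr] <<- f; tr_ssq[n_tr] <<- 0; tr_nstep[n_tr] <<- 0
    tr_open[n_tr] <<- TRUE
    traj_of[li] <<- n_tr
  }

  for (fi in seq_along(frames)) {
    f <- frames[fi]
    ii <- idx_by_frame[[fi]]
    open <- which(tr_open[seq_len(n_tr)])
    stale <- open[f - tr_last[open] > max_gap + 1L]
    tr_open[stale] <- FALSE
    open <- setdiff(open, stale)
    if (length(open)) {
      gap <- f - tr_last[open]
      # blended mean squared per-frame step: prior (weight w0) + observed
      s2 <- (w0 * s2_init + tr_ssq[open]) / (w0 + tr_nstep[open])
      gate <- gate_factor * sqrt(s2 * gap)
      maxgate <- max(gate)
      pr <- cross_pairs_cpp(tr_x[open], tr_y[open], x[ii], y[ii], maxgate)
      keep <- pr$dist <= gate[pr$i]
      pi <- pr$i[keep]; pj <- pr$j[keep]; pd <- pr$dist[keep]
      if (length(pi)) {
        match <- link_assign_cpp(length(open), length(ii), pi, pj,
                                 pd^2, gate^2)
      } else match <- integer(length(open))
      linked <- which(match > 0)
      for (a in linked) {
        ti <- open[a]; li <- ii[match[a]]
        g <- f - tr_last[ti]
        d2 <- (x[li] - tr_x[ti])^2 + (y[li] - tr_y[ti])^2
        tr_nstep[ti] <- tr_nstep[ti] + 1
        tr_ssq[ti] <- tr_ssq[ti] + d2 / g
        tr_x[ti] <- x[li]; tr_y[ti] <- y[li]; tr_last[ti] <- f
        traj_of[li] <- ti
      }
      taken <- logical(length(ii))
      taken[match[linked]] <- TRUE
      for (b in which(!taken)) new_traj(ii[b], f)
    } else {
      for (b in seq_along(ii)) new_traj(ii[b], f)
    }
  }

  out <- locs[ord, , drop = FALSE]
  out$trajectory_id <- traj_of
  out <- out[order(out$trajectory_id, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mean squared displacement of one trajectory
#'
#' Time-averaged MSD: for lag `k` frames, the mean over all pairs of
#' localizations `k` frames apart whose intervening frames are fully
#' observed (pairs spanning observation gaps are excluded).  Each lag also
#' carries the standard finite-trajectory variance factor of the MSD
#' estimator for free diffusion, `(2k^2 + 1) / (3k (N - k + 1))`, from
#' which inverse-variance fit weights are formed.
#'
#' @param traj data.frame of one trajectory (`frame`, `x_um`, `y_um`).
#' @param max_lag Maximum lag in frames (default 5).
#' @return data.frame `lag` (frames), `msd` (um^2), `n_pairs`,
#'   `var_factor`; lags with no valid pairs are omitted.
#' @export
compute_msd <- function(traj, max_lag = 5) {
  o <- order(traj$frame)
  fr <- traj$frame[o]; x <- traj$x_um[o]; y <- traj$y_um[o]
  if (anyDuplicated(fr)) stop("duplicate frames in trajectory")
  N <- length(fr)
  f0 <- fr - fr[1]
  pos_x <- rep(NA_real_, max(f0) + 1); pos_y <- pos_x
  pos_x[f0 + 1] <- x; pos_y[f0 + 1] <- y
  present <- !is.na(pos_x)
  # run[i]: number of consecutive present frames starting at i
  run <- integer(length(present))
  acc <- 0L
  for (i in rev(seq_along(present))) {
    acc <- if (present[i]) acc + 1L else 0L
    run[i] <- acc
  }
  out <- lapply(seq_len(min(max_lag, length(present) - 1)), function(k) {
    starts <- which(run > k)
    starts <- starts[starts + k <= length(present)]
    if (!length(starts)) return(NULL)
    d2 <- (pos_x[starts + k] - pos_x[starts])^2 +
          (pos_y[starts + k] - pos_y[starts])^2
    data.frame(lag = k, msd = mean(d2), n_pairs = length(d2),
               var_factor = (2 * k^2 + 1) / (3 * k * (N - k + 1)))
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(lag = integer(0), msd = numeric(0),
                      n_pairs = integer(0), var_factor = numeric(0))
  out
}

#' Fit the localization-error-corrected diffusion model to an MSD curve
#'
#' Weighted least squares of the linear model
#' `msd(tau) = 4 D tau - 4/3 D dt + 4 eps^2`
#' on the first `n_lags` lags, where `tau = k dt` is the time lag, `dt`
#' the camera exposure time and `eps` the localization precision.  The
#' `-4/3 D dt` term corrects for motion blur during the finite exposure and
#' `4 eps^2` for the static localization error.  Weights are inverse
#' expected variances; after an initial fit they are recomputed from the
#' model-implied MSD (two-pass reweighting) so that noisy measured values
#' do not bias the slope.  If the implied `eps^2` is negative, `epsilon`
#' is reported as 0 and flagged.
#'
#' @param msd data.frame from [compute_msd()].
#' @param dt Frame interval / exposure time in seconds.
#' @param n_lags Number of lags used (default 5, i.e. tau < 160 ms at
#'   32 ms/frame).
#' @return List with `D` (um^2/s), `epsilon` (um), `epsilon_clipped`
#'   (logical), `n_lags_used`, `residual` (weighted RSS), `msd` (the lags
#'   used, with weights).
#' @export
fit_diffusion <- function(msd, dt, n_lags = 5) {
  m <- msd[msd$lag <= n_lags & msd$n_pairs > 0, , drop = FALSE]
  if (nrow(m) < 2) return(NULL)
  tau <- m$lag * dt
  floor_msd <- max(m$msd, 0) * 1e-6 + 1e-12
  w <- 1 / (pmax(m$msd, floor_msd)^2 * m$var_factor)
  fit <- stats::lm.wfit(cbind(1, tau), m$msd, w)
  a <- fit$coefficients[1]; b <- fit$coefficients[2]
  # second pass with model-implied weights, immune to measurement noise in
  # the weights; kept only when the fitted model is usable as a variance
  pred <- a + b * tau
  if (all(is.finite(pred)) && all(pred > 0)) {
    w <- 1 / (pred^2 * m$var_factor)
    fit <- stats::lm.wfit(cbind(1, tau), m$msd, w)
    a <- fit$coefficients[1]; b <- fit$coefficients[2]
  }
  if (!is.finite(a) || !is.finite(b)) return(NULL)
  D <- b / 4
  e2 <- (a + (4 / 3) * D * dt) / 4
  clipped <- e2 < 0
  m$weight <- w
  list(D = unname(D),
       epsilon = if (clipped) 0 else unname(sqrt(e2)),
       epsilon_clipped = clipped,
       n_lags_used = nrow(m),
       residual = sum(w * (m$msd - (a + b * tau))^2),
       msd = m)
}

#' Per-trajectory diffusion fits and ensemble summary
#'
#' Applies [compute_msd()] and [fit_diffusion()] to every trajectory
#' longer than `min_frames` frames and summarises the mobile diffusion
#' coefficient by the median (robust against the heavy right tail of
#' short-trajectory estimates).  Trajectories with a negative fitted `D`
#' are flagged and excluded from the summary.  An ensemble fit (pooled
#' MSD across trajectories, weighted by pair counts) is also returned.
#'
#' @param locs Localization data.frame with `trajectory_id` from
#'   [link_trajectories()].
#' @param frame_interval Frame interval in seconds.
#' @param min_frames Trajectories must exceed this many localizations to
#'   be fitted (default 10).
#' @param n_lags Lags used per fit (default 5).
#' @return List with `fits` (data.frame `trajectory_id`, `D_um2_s`,
#'   `epsilon_um`, `n_frames`), `summary` (list `median_D`, `iqr_D`, `n`,
#'   `n_negative_D`) and `ensemble` (ensemble-MSD fit).
#' @export
fit_trajectories <- function(locs, frame_interval = 0.032, min_frames = 10,
                             n_lags = 5) {
  sp <- split(locs[, c("frame", "x_um", "y_um")], locs$trajectory_id)
  sp <- sp[vapply(sp, nrow, integer(1)) > min_frames]
  rows <- vector("list", length(sp))
  pooled <- stats::setNames(vector("list", n_lags), seq_len(n_lags))
  pooled_n <- numeric(n_lags); pooled_sum <- numeric(n_lags)
  Ns <- numeric(0)
  for (i in seq_along(sp)) {
    m <- compute_msd(sp[[i]], max_lag = n_lags)
    fit <- fit_diffusion(m, frame_interval, n_lags)
    if (is.null(fit)) next
    rows[[i]] <- data.frame(trajectory_id = names(sp)[i],
                            D_um2_s = fit$D, epsilon_um = fit$epsilon,
                            n_frames = nrow(sp[[i]]))
    pooled_sum[m$lag] <- pooled_sum[m$lag] + m$msd * m$n_pairs
    pooled_n[m$lag] <- pooled_n[m$lag] + m$n_pairs
    Ns <- c(Ns, nrow(sp[[i]]))
  }
  fits <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(fits))
    fits <- data.frame(trajectory_id = character(0), D_um2_s = numeric(0),
                       epsilon_um = numeric(0), n_frames = integer(0))
  ok <- fits$D_um2_s > 0
  summary <- list(
    median_D = if (any(ok)) stats::median(fits$D_um2_s[ok]) else NA_real_,
    iqr_D = if (any(ok)) stats::IQR(fits$D_um2_s[ok]) else NA_real_,
    n = sum(ok), n_negative_D = sum(!ok))
  ens <- NULL
  lag_ok <- which(pooled_n > 0)
  if (length(lag_ok) >= 2) {
    Nbar <- mean(Ns)
    ens_msd <- data.frame(lag = lag_ok, msd = pooled_sum[lag_ok] / pooled_n[lag_ok],
                          n_pairs = pooled_n[lag_ok],
                          var_factor = (2 * lag_ok^2 + 1) /
                            (3 * lag_ok * pmax(Nbar - lag_ok + 1, 1)) /
                            max(length(Ns), 1))
    ens <- fit_diffusion(ens_msd, frame_interval, n_lags)
  }
  list(fits = fits, summary = summary, ensemble = ens)
}
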