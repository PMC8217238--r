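#' Simulate ground-truth trajectories and observed localizations
#'
#' Generates two-state (mobile/arrested) Brownian trajectories for labeled
#' receptor complexes and the noisy localizations an imaging experiment
#' would observe.  All subunits of a complex share one true position
#' sequence; each labeled subunit emits in exactly one spectral channel and
#' its observed positions are the true positions plus independent Gaussian
#' localization noise.  Mobile steps per axis are Gaussian with variance
#' `2 * d_free * frame_interval`; arrested complexes stay inside a disc of
#' the trap's `domain_diameter` centred at the arrest entry point, moving by
#' residual diffusion `d_trap` (Gaussian proposals rejected at the disc
#' boundary, which leaves the uniform-in-disc law invariant).
#'
#' Only complexes carrying at least one label are simulated: unlabeled
#' complexes are invisible to every downstream stage and their number is
#' implied by the scenario's density book-keeping.
#'
#' @param scenario A [sim_scenario()].
#' @return A list with
#'   \describe{
#'     \item{localizations}{data.frame `frame` (0-based), `x_um`, `y_um`,
#'       `channel` ("A"/"B"), `particle_id` (emitter), `complex_id`.}
#'     \item{truth}{list with `positions` (per-complex true positions and
#'       state per frame: `frame`, `complex_id`, `x_um`, `y_um`, `state`
#'       where 0 = mobile, 1 = arrested), `particles` (one row per labeled
#'       emitter: `particle_id`, `complex_id`, `complex_size`, `channel`)
#'       and `complexes` (`complex_id`, `size`, `n_labels_a`, `n_labels_b`).}
#'   }
#' @export
simulate_trajectories <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  withr::with_seed(scenario$seed, simulate_trajectories_impl(scenario))
}

simulate_trajectories_impl <- function(scenario) {
  s <- scenario
  sizes <- as.integer(names(s$oligomer_size_dist))
  nfr <- s$n_frames
  dt <- s$frame_interval
  # draw complexes until the expected labeled-emitter budget is realised
  size <- sizes[sample.int(length(sizes), s$n_complexes, replace = TRUE,
                           prob = s$oligomer_size_dist)]
  n_lab <- stats::rbinom(length(size), size, s$p_label)
  keep <- n_lab > 0
  size <- size[keep]; n_lab <- n_lab[keep]
  nc <- length(size)
  if (nc == 0)
    stop("no labeled complexes realised; increase density or p_label")
  n_a <- stats::rbinom(nc, n_lab, s$color_split)
  n_b <- n_lab - n_a

  tm <- s$trap
  R <- tm$domain_diameter / 2
  sd_free <- sqrt(2 * s$d_free * dt)
  sd_trap <- sqrt(2 * tm$d_trap * dt)

  x <- matrix(0, nfr, nc); y <- matrix(0, nfr, nc)
  st <- matrix(0L, nfr, nc)
  cx <- numeric(nc); cy <- numeric(nc)  # trap centres (valid when arrested)

  x[1, ] <- stats::runif(nc, 0, s$fov[1])
  y[1, ] <- stats::runif(nc, 0, s$fov[2])
  # initial state from the stationary distribution of the two-state chain
  pi_arr <- if (tm$p_arrest + tm$p_release > 0)
    tm$p_arrest / (tm$p_arrest + tm$p_release) else 0
  st[1, ] <- as.integer(stats::runif(nc) < pi_arr)
  cx <- x[1, ]; cy <- y[1, ]

  wrap <- function(v, L) switch(s$boundary,
    periodic = v %% L,
    reflecting = {
      v <- v %% (2 * L)
      ifelse(v > L, 2 * L - v, v)
    },
    none = v)

  for (f in 2:nfr) {
    prev <- st[f - 1, ]
    u <- stats::runif(nc)
    newst <- ifelse(prev == 0L,
                    as.integer(u < tm$p_arrest),
                    as.integer(u >= tm$p_release))
    entering <- newst == 1L & prev == 0L
    cx[entering] <- x[f - 1, entering]
    cy[entering] <- y[f - 1, entering]

    mob <- newst == 0L
    dx <- numeric(nc); dy <- numeric(nc)
    if (any(mob)) {
      dx[mob] <- stats::rnorm(sum(mob), 0, sd_free)
      dy[mob] <- stats::rnorm(sum(mob), 0, sd_free)
    }
    xf <- x[f - 1, ] + dx
    yf <- y[f - 1, ] + dy
    arr <- which(!mob)
    if (length(arr)) {
      px <- x[f - 1, arr] + stats::rnorm(length(arr), 0, sd_trap)
      py <- y[f - 1, arr] + stats::rnorm(length(arr), 0, sd_trap)
      inside <- (px - cx[arr])^2 + (py - cy[arr])^2 <= R^2
      # Metropolis step targeting the uniform law on the disc:
      # proposals outside are rejected and the complex stays put
      xf[arr] <- ifelse(inside, px, x[f - 1, arr])
      yf[arr] <- ifelse(inside, py, y[f - 1, arr])
    }
    if (any(mob)) {
      xf[mob] <- wrap(xf[mob], s$fov[1])
      yf[mob] <- wrap(yf[mob], s$fov[2])
    }
    x[f, ] <- xf; y[f, ] <- yf
    st[f, ] <- newst
  }

  complexes <- data.frame(complex_id = seq_len(nc), size = size,
                          n_labels_a = n_a, n_labels_b = n_b)
  particles <- data.frame(
    particle_id = seq_len(sum(n_lab)),
    complex_id = rep(seq_len(nc), n_lab),
    complex_size = rep(size, n_lab),
    channel = unlist(lapply(seq_len(nc), function(i)
      c(rep("A", n_a[i]), rep("B", n_b[i]))), use.names = FALSE),
    stringsAsFactors = FALSE)

  npart <- nrow(particles)
  frame0 <- rep(seq_len(nfr) - 1L, npart)
  cid <- rep(particles$complex_id, each = nfr)
  obs_x <- as.vector(x[, particles$complex_id])
  obs_y <- as.vector(y[, particles$complex_id])
  if (s$loc_noise_sigma > 0) {
    obs_x <- obs_x + stats::rnorm(length(obs_x), 0, s$loc_noise_sigma)
    obs_y <- obs_y + stats::rnorm(length(obs_y), 0, s$loc_noise_sigma)
  }
  localizations <- data.frame(
    frame = frame0,
    x_um = obs_x, y_um = obs_y,
    channel = rep(particles$channel, each = nfr),
    particle_id = rep(particles$particle_id, each = nfr),
    complex_id = cid,
    stringsAsFactors = FALSE)
  localizations <- localizations[order(localizations$frame,
                                       localizations$particle_id), ]
  rownames(localizations) <- NULL

  positions <- data.frame(
    frame = rep(seq_len(nfr) - 1L, nc),
    complex_id = rep(seq_len(nc), each = nfr),
    x_um = as.vector(x), y_um = as.vector(y),
    state = as.vector(st))

  list(localizations = localizations,
       truth = list(positions = positions, particles = particles,
                    complexes = complexes))
}

#' Simulate stochastic two-color labeling of receptor complexes
#'
#' Forward model for dual-color co-tracking statistics: each of the `n`
#' subunits of a complex is labeled independently with probability
#' `p_label` and a label is assigned to channel A with probability
#' `color_split` (otherwise B).  A complex is "dual-labeled" when it
#' carries at least one A label and at least one B label, which is the
#' condition for it to be detectable by two-color co-tracking.
#'
#' @param n Complex size (number of subunits), >= 1.
#' @param p_label Per-subunit labeling probability.
#' @param color_split Probability that a label falls in channel A.
#' @param n_complexes Number of complexes to simulate.
#' @param seed Integer seed.
#' @return List with `counts` (data.frame `n_a`, `n_b` per complex) and
#'   `dual_fraction`, the realised fraction of dual-labeled complexes.
#' @seealso [dual_labeled_fraction()] for the exact closed form.
#' @export
simulate_oligomer_labeling <- function(n, p_label, color_split,
                                       n_complexes, seed = 1L) {
  if (n < 1) stop("n must be >= 1")
  if (n_complexes < 1) stop("n_complexes must be >= 1")
  if (p_label < 0 || p_label > 1 || color_split < 0 || color_split > 1)
    stop("probabilities must lie in [0, 1]")
  withr::with_seed(seed, {
    lab <- stats::rbinom(n_complexes, n, p_label)
    n_a <- stats::rbinom(n_complexes, lab, color_split)
    n_b <- lab - n_a
    data.frame(n_a = n_a, n_b = n_b)
  }) -> counts
  list(counts = counts,
       dual_fraction = mean(counts$n_a >= 1 & counts$n_b >= 1))
}

#' Exact dual-labeled fraction for a complex of size n
#'
#' Closed-form probability that a complex of `n` subunits, each labeled
#' with probability `p_label` and split between channels with probability
#' `color_split` for A, carries at least one A and at least one B label:
#' by inclusion-exclusion,
#' `1 - (1 - p*s)^n - (1 - p*(1-s))^n + (1 - p)^n`.
#'
#' @inheritParams simulate_oligomer_labeling
#' @return Probability in `[0, 1]` (vectorised over `n`).
#' @export
dual_labeled_fraction <- function(n, p_label, color_split = 0.5) {
  pa <- p_label * color_split
  pb <- p_label * (1 - color_split)
  1 - (1 - pa)^n - (1 - pb)^n + (1 - p_label)^n
}

#' Render synthetic single-molecule movies
#'
#' Places an integrated 2D Gaussian point-spread function for every emitter
#' on a pixel grid and applies Poisson shot noise on signal plus background
#' with optional Gaussian read noise, emulating an EMCCD acquisition.
#' Emitters outside the field of view contribute only the part of their PSF
#' that falls inside (they are silently clipped).
#'
#' @param emitters data.frame with columns `frame` (0-based), `x_um`,
#'   `y_um` and optionally `channel`; e.g. the `localizations` element of
#'   [simulate_trajectories()] (run with `loc_noise_sigma = 0` so spots are
#'   rendered at true positions).
#' @param fov Field of view (x, y) in micrometers.
#' @param n_frames Number of frames to render.
#' @param pixel_size Pixel size in micrometers (default 0.1067, a 16 um
#'   EMCCD pixel behind a 150x objective).
#' @param psf_sigma PSF standard deviation in micrometers (default 0.139).
#' @param photons_per_spot Expected photons per emitter per frame.
#' @param background Background photons per pixel per frame.
#' @param read_noise_sd Gaussian read noise (counts), 0 to disable.
#' @param poisson Apply Poisson shot noise (`TRUE`) or render the noiseless
#'   expectation (`FALSE`).
#' @param frame_interval Frame interval stored in the stack metadata.
#' @param seed Integer seed.
#' @return A named list of [frame_stack()] objects, one per channel.
#' @export
render_movie <- function(emitters, fov, n_frames,
                         pixel_size = 0.1067, psf_sigma = 0.139,
                         photons_per_spot = 500, background = 10,
                         read_noise_sd = 0, poisson = TRUE,
                         frame_interval = 0.032, seed = 1L) {
  if (psf_sigma <= 0) stop("psf_sigma must be > 0")
  if (photons_per_spot < 0) stop("photons_per_spot must be >= 0")
  if (background < 0) stop("background must be >= 0")
  if (is.null(emitters$channel))
    emitters$channel <- rep("A", nrow(emitters))
  channels <- sort(unique(emitters$channel))
  if (length(channels) == 0) channels <- "A"
  nrow_px <- as.integer(ceiling(fov[2] / pixel_size))
  ncol_px <- as.integer(ceiling(fov[1] / pixel_size))
  withr::with_seed(seed, {
    out <- lapply(channels, function(ch) {
      e <- emitters[emitters$channel == ch, , drop = FALSE]
      px <- array(0, dim = c(n_frames, nrow_px, ncol_px))
      for (f in seq_len(n_frames)) {
        img <- matrix(background, nrow_px, ncol_px)
        ef <- e[e$frame == f - 1L, , drop = FALSE]
        for (k in seq_len(nrow(ef))) {
          img <- img + spot_profile(ef$x_um[k], ef$y_um[k], nrow_px, ncol_px,
                                    pixel_size, psf_sigma, photons_per_spot)
        }
        if (poisson) img <- matrix(stats::rpois(length(img), img),
                                   nrow_px, ncol_px)
        if (read_noise_sd > 0)
          img <- img + stats::rnorm(length(img), 0, read_noise_sd)
        px[f, , ] <- img
      }
      frame_stack(px, pixel_size = pixel_size,
                  frame_interval = frame_interval, channel = ch)
    })
    names(out) <- channels
    out
  })
}

# Integrated Gaussian PSF of one emitter on the pixel grid.  Pixel (r, c)
# (1-based) is centred at x = (c-1)*ps, y = (r-1)*ps and spans +- ps/2.
spot_profile <- function(x0, y0, nrow_px, ncol_px, ps, sigma, photons) {
  out <- matrix(0, nrow_px, ncol_px)
  half <- ceiling(5 * sigma / ps)
  c0 <- round(x0 / ps) + 1; r0 <- round(y0 / ps) + 1
  cs <- max(1, c0 - half):min(ncol_px, c0 + half)
  rs <- max(1, r0 - half):min(nrow_px, r0 + half)
  if (length(cs) == 0 || length(rs) == 0) return(out)
  fx <- stats::pnorm(((cs - 1) * ps + ps / 2 - x0) / sigma) -
        stats::pnorm(((cs - 1) * ps - ps / 2 - x0) / sigma)
  fy <- stats::pnorm(((rs - 1) * ps + ps / 2 - y0) / sigma) -
        stats::pnorm(((rs - 1) * ps - ps / 2 - y0) / sigma)
  out[rs, cs] <- photons * (fy %o% fx)
  out
}

#' Simulate FRAP bleach and control ROI intensity time series
#'
#' Ideal recovery model: the normalized post-bleach signal recovers as
#' `mobile_fraction * (1 - exp(-recovery_rate * t))` towards the mobile
#' plateau, on top of the residual intensity left by a bleach of depth
#' `bleach_depth`.  Both bleach and control ROIs decay by
#' `exp(-acquisition_bleach_rate * t)` over the whole acquisition, and
#' additive Gaussian noise is applied.
#'
#' @param mobile_fraction Fraction of fluorophores free to exchange, in
#'   `[0, 1]`.
#' @param recovery_rate Recovery rate constant (1/s).
#' @param bleach_depth Fraction of the pre-bleach intensity removed by the
#'   bleach pulse, in `(0, 1]`.
#' @param acquisition_bleach_rate Residual acquisition photobleaching rate
#'   (1/s) affecting both ROIs.
#' @param n_pre,n_post Number of pre- and post-bleach frames (`n_pre >= 1`).
#' @param dt Frame interval (s).
#' @param noise_sd Additive Gaussian noise, in units of the pre-bleach
#'   intensity (which is 1).
#' @param seed Integer seed.
#' @return List with `bleach` and `control` intensity vectors (pre-bleach
#'   frames first), `time` (s, 0 at the first post-bleach frame, negative
#'   during pre-bleach), and `n_pre`.
#' @export
simulate_frap <- function(mobile_fraction, recovery_rate = 0.1,
                          bleach_depth = 0.8, acquisition_bleach_rate = 0,
                          n_pre = 10, n_post = 100, dt = 0.5,
                          noise_sd = 0, seed = 1L) {
  if (mobile_fraction < 0 || mobile_fraction > 1)
    stop("mobile_fraction must lie in [0, 1]")
  if (bleach_depth <= 0 || bleach_depth > 1)
    stop("bleach_depth must lie in (0, 1]")
  if (n_pre < 1) stop("n_pre must be >= 1 (pre-bleach mean undefined)")
  t_post <- (seq_len(n_post) - 1) * dt
  t_pre <- -rev(seq_len(n_pre)) * dt
  t_all <- c(t_pre, t_post)
  ideal_pre <- rep(1, n_pre)
  ideal_post <- (1 - bleach_depth) +
    bleach_depth * mobile_fraction * (1 - exp(-recovery_rate * t_post))
  decay <- exp(-acquisition_bleach_rate * (t_all - t_all[1]))
  bleach <- c(ideal_pre, ideal_post) * decay
  control <- decay
  withr::with_seed(seed, {
    if (noise_sd > 0) {
      bleach <- bleach + stats::rnorm(length(bleach), 0, noise_sd)
      control <- control + stats::rnorm(length(control), 0, noise_sd)
    }
    list(bleach = bleach, control = control, time = t_all, n_pre = n_pre)
  })
}
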