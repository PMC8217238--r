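#' Detect single-molecule signals in one frame at a fixed false-positive rate
#'
#' Pixel-wise generalized likelihood-ratio test of a fixed-width Gaussian
#' peak plus constant background (H1) against constant background alone
#' (H0), evaluated in a `box` x `box` window around every pixel against the
#' locally estimated noise.  With Gaussian noise the statistic is exactly
#' Student-t distributed with `box^2 - 2` degrees of freedom under H0, so
#' the default threshold is the corresponding upper `alpha_det` quantile;
#' a Monte-Carlo refined threshold from
#' [calibrate_detection_threshold()] can be supplied instead.  Candidates
#' are reduced to 8-connected local maxima of the statistic (ties broken in
#' row-major order) and are only reported where the full box fits inside
#' the frame.
#'
#' @param frame Numeric matrix (one image; rows = y, columns = x).
#' @param alpha_det Per-pixel false-positive rate, default `1e-6`.
#' @param box Odd evaluation-box size in pixels, default 9.
#' @param psf_sigma_px PSF standard deviation in pixels (default 1.3).
#' @param threshold Optional explicit statistic threshold overriding the
#'   analytic `alpha_det` quantile.
#' @return data.frame `row`, `col` (1-based pixel indices) and `statistic`,
#'   ordered by decreasing statistic.
#' @export
detect_particles <- function(frame, alpha_det = 1e-6, box = 9,
                             psf_sigma_px = 1.3, threshold = NULL) {
  if (!is.matrix(frame)) stop("frame must be a matrix")
  if (box %% 2 != 1) stop("box must be odd")
  if (nrow(frame) < box || ncol(frame) < box)
    stop("frame smaller than the evaluation box")
  if (alpha_det <= 0 || alpha_det >= 1) stop("alpha_det must be in (0, 1)")
  stat <- detection_statistic(frame, box, psf_sigma_px)
  if (is.null(threshold))
    threshold <- stats::qt(1 - alpha_det, df = box^2 - 2)
  cand <- which(local_maxima(stat) & stat > threshold, arr.ind = TRUE)
  out <- data.frame(row = cand[, 1], col = cand[, 2],
                    statistic = stat[cand])
  out[order(-out$statistic), , drop = FALSE]
}

# GLRT/matched-filter t statistic per pixel via box convolutions.
# Template: integrated Gaussian, mean-centred; amplitude estimated by least
# squares, noise sd from the box residuals (df = n - 2).
detection_statistic <- function(frame, box, psf_sigma_px) {
  h <- (box - 1) / 2
  g <- psf_template(box, psf_sigma_px)
  gt <- g - mean(g)
  g2 <- sum(gt^2)
  n <- box^2
  ones <- matrix(1, box, box)
  s1 <- EBImage::filter2(frame, ones, boundary = "replicate")
  s2 <- EBImage::filter2(frame^2, ones, boundary = "replicate")
  # filter2 computes correlation with the kernel centred on each pixel
  sg <- EBImage::filter2(frame, gt, boundary = "replicate")
  rss <- pmax(s2 - s1^2 / n - sg^2 / g2, 0)
  sigma <- sqrt(rss / (n - 2))
  stat <- ifelse(sigma > 0, sg / (sqrt(g2) * sigma), 0)
  # invalidate the margin where the box does not fit
  stat[c(seq_len(h), nrow(stat) - seq_len(h) + 1), ] <- -Inf
  stat[, c(seq_len(h), ncol(stat) - seq_len(h) + 1)] <- -Inf
  stat
}

psf_template <- function(box, sigma) {
  h <- (box - 1) / 2
  u <- (-h):h
  f <- stats::pnorm((u + 0.5) / sigma) - stats::pnorm((u - 0.5) / sigma)
  f %o% f
}

# TRUE at 8-connected local maxima; equal-valued neighbours are resolved in
# favour of the smaller row-major index.
local_maxima <- function(stat) {
  nr <- nrow(stat); nc <- ncol(stat)
  idx <- (row(stat) - 1) * nc + col(stat)  # row-major order index
  ok <- is.finite(stat)
  shift <- function(m, dr, dc, fill) {
    out <- matrix(fill, nr, nc)
    rs <- seq_len(nr); cs <- seq_len(nc)
    rsrc <- rs - dr; csrc <- cs - dc
    rok <- rsrc >= 1 & rsrc <= nr; cok <- csrc >= 1 & csrc <= nc
    out[rs[rok], cs[cok]] <- m[rsrc[rok], csrc[cok]]
    out
  }
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- shift(stat, dr, dc, -Inf)
    nbidx <- shift(idx, dr, dc, Inf)
    ok <- ok & (stat > nb | (stat == nb & idx < nbidx))
  }
  ok
}

#' Monte-Carlo calibration of the detection threshold
#'
#' Simulates pure Gaussian-noise evaluation boxes, computes the detection
#' statistic for each, and returns the empirical `1 - alpha_det` quantile.
#' Useful to refine the asymptotic Student-t threshold when the noise model
#' deviates from iid Gaussian assumptions.
#'
#' @inheritParams detect_particles
#' @param n_sim Number of simulated boxes; must be at least
#'   `100 / alpha_det` for a stable tail quantile.
#' @param seed Integer seed.
#' @return Scalar threshold on the detection statistic.
#' @export
calibrate_detection_threshold <- function(alpha_det = 1e-3, box = 9,
                                          psf_sigma_px = 1.3,
                                          n_sim = ceiling(100 / alpha_det),
                                          seed = 1L) {
  if (n_sim < 100 / alpha_det)
    stop(sprintf("n_sim must be >= %d for alpha_det = %g",
                 ceiling(100 / alpha_det), alpha_det))
  g <- psf_template(box, psf_sigma_px)
  gt <- as.vector(g - mean(g))
  g2 <- sum(gt^2)
  n <- box^2
  withr::with_seed(seed, {
    x <- matrix(stats::rnorm(n_sim * n), nrow = n)
    sg <- as.vector(crossprod(gt, x))
    s1 <- colSums(x); s2 <- colSums(x^2)
    rss <- pmax(s2 - s1^2 / n - sg^2 / g2, 0)
    tt <- sg / (sqrt(g2) * sqrt(rss / (n - 2)))
    unname(stats::quantile(tt, 1 - alpha_det, type = 8))
  })
}

#' Sub-pixel localization of detected candidates
#'
#' Least-squares fit of an integrated 2D Gaussian with fixed width
#' (amplitude, constant background, and sub-pixel centre free) in the
#' evaluation box around each candidate, by Levenberg-Marquardt.  The
#' localization precision is estimated from the fit covariance
#' (Cramer-Rao style).  Fits that fail to converge or whose centre leaves
#' the box are dropped and counted.
#'
#' @param frame Numeric matrix.
#' @param candidates data.frame from [detect_particles()].
#' @param psf_sigma_px Fixed PSF standard deviation in pixels.
#' @param pixel_size Pixel size in micrometers.
#' @param box Fit window size (odd), default 9.
#' @return data.frame with `x_um`, `y_um` (origin at the centre of pixel
#'   (1,1); x along columns), `precision_um`, `intensity` (photons),
#'   `background` (photons/px), `statistic`; attribute `n_dropped` counts
#'   discarded fits.
#' @export
localize <- function(frame, candidates, psf_sigma_px = 1.3,
                     pixel_size = 0.1067, box = 9) {
  h <- (box - 1) / 2
  n <- nrow(candidates)
  out <- vector("list", n)
  dropped <- 0L
  for (k in seq_len(n)) {
    r0 <- candidates$row[k]; c0 <- candidates$col[k]
    rs <- (r0 - h):(r0 + h); cs <- (c0 - h):(c0 + h)
    if (min(rs) < 1 || min(cs) < 1 || max(rs) > nrow(frame) ||
        max(cs) > ncol(frame)) { dropped <- dropped + 1L; next }
    z <- frame[rs, cs]
    if (max(z) == min(z)) { dropped <- dropped + 1L; next }
    fit <- fit_gaussian_spot(z, psf_sigma_px)
    if (is.null(fit) || abs(fit$dx) > h || abs(fit$dy) > h) {
      dropped <- dropped + 1L; next
    }
    out[[k]] <- data.frame(
      x_um = (c0 - 1 + fit$dx) * pixel_size,
      y_um = (r0 - 1 + fit$dy) * pixel_size,
      precision_um = fit$precision_px * pixel_size,
      intensity = fit$amplitude,
      background = fit$background,
      statistic = candidates$statistic[k])
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res))
    res <- data.frame(x_um = numeric(0), y_um = numeric(0),
                      precision_um = numeric(0), intensity = numeric(0),
                      background = numeric(0), statistic = numeric(0))
  attr(res, "n_dropped") <- dropped
  res
}

# LM fit of A * psf(dx, dy) + b on a (2h+1)^2 patch; offsets relative to
# the patch centre pixel.  Residuals are weighted by the model-implied
# shot-noise sd (Poisson variance ~ expected counts) so the covariance of
# the fit reflects the true localization uncertainty.  Returns NULL on
# failure.
fit_gaussian_spot <- function(z, sigma) {
  box <- nrow(z)
  h <- (box - 1) / 2
  u <- (-h):h
  model <- function(p) {
    fx <- stats::pnorm((u - p[3] + 0.5) / sigma) -
          stats::pnorm((u - p[3] - 0.5) / sigma)
    fy <- stats::pnorm((u - p[4] + 0.5) / sigma) -
          stats::pnorm((u - p[4] - 0.5) / sigma)
    p[2] + p[1] * (fy %o% fx)
  }
  vfloor <- max(stats::var(as.vector(z)) * 1e-3, 1e-9)
  resid_fn <- function(p) {
    mu <- model(p)
    as.vector((z - mu) / sqrt(pmax(mu, vfloor)))
  }
  b0 <- stats::median(z)
  a0 <- max(sum(z - b0), max(z) - b0)
  fit <- tryCatch(
    minpack.lm::nls.lm(par = c(a0, b0, 0, 0), fn = resid_fn,
                       control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit) || fit$info %in% c(0, 9)) return(NULL)
  p <- fit$par
  # covariance from the weighted Jacobian at the solution; with correct
  # Poisson weights the residual variance is ~1, so the dispersion factor
  # mainly absorbs model misspecification
  prec <- tryCatch({
    dof <- length(z) - 4
    s2 <- fit$deviance / max(dof, 1)
    cv <- max(s2, 1) * solve(fit$hessian)
    sqrt(pmax((cv[3, 3] + cv[4, 4]) / 2, 0))
  }, error = function(e) NA_real_)
  list(amplitude = p[1], background = p[2], dx = p[3], dy = p[4],
       precision_px = prec)
}

#' Detect and localize particles in every frame of a stack
#'
#' Convenience wrapper running [detect_particles()] and [localize()]
#' frame by frame.
#'
#' @param stack A [frame_stack()].
#' @inheritParams detect_particles
#' @param psf_sigma_um PSF standard deviation in micrometers; converted to
#'   pixels via the stack's pixel size.
#' @param threshold Optional explicit statistic threshold.
#' @return Localization data.frame with columns `frame` (0-based), `x_um`,
#'   `y_um`, `precision_um`, `intensity`, `background`, `channel`.
#' @export
localize_stack <- function(stack, alpha_det = 1e-6, box = 9,
                           psf_sigma_um = 0.139, threshold = NULL) {
  stopifnot(inherits(stack, "frame_stack"))
  sig_px <- psf_sigma_um / stack$pixel_size
  nfr <- dim(stack$pixels)[1]
  res <- vector("list", nfr)
  for (f in seq_len(nfr)) {
    img <- stack$pixels[f, , ]
    cand <- detect_particles(img, alpha_det = alpha_det, box = box,
                             psf_sigma_px = sig_px, threshold = threshold)
    if (nrow(cand) == 0) next
    loc <- localize(img, cand, psf_sigma_px = sig_px,
                    pixel_size = stack$pixel_size, box = box)
    if (nrow(loc) == 0) next
    loc$frame <- f - 1L
    res[[f]] <- loc
  }
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) == 0)
    return(data.frame(frame = integer(0), x_um = numeric(0),
                      y_um = numeric(0), precision_um = numeric(0),
                      intensity = numeric(0), background = numeric(0),
                      channel = character(0)))
  out <- do.call(rbind, res)
  out$channel <- stack$channel
  out[, c("frame", "x_um", "y_um", "precision_um", "intensity",
          "background", "channel")]
}

#' Render a super-resolution localization image
#'
#' Histograms localizations from a window of frames onto an upsampled
#' pixel grid and blurs with a Gaussian of the mean localization precision
#' (or an explicit `blur_sd`).  The blur kernel is normalized on the
#' discrete grid, so total image mass equals the number of rendered
#' localizations (up to clipping of spots within the kernel radius of the
#' image border).
#'
#' @param locs Localization data.frame (`frame`, `x_um`, `y_um`, optionally
#'   `precision_um`).
#' @param fov Field of view (x, y) in micrometers.
#' @param pixel_size Camera pixel size in micrometers.
#' @param n_frames_window Only localizations with
#'   `frame < n_frames_window` are rendered (default 500).
#' @param upsampling Integer upsampling factor (>= 1), default 10.
#' @param blur_sd Blur standard deviation in micrometers; default is the
#'   mean localization precision (0.02 if unavailable).
#' @return Numeric matrix (rows = y) of the rendered image.
#' @export
render_smlm_image <- function(locs, fov, pixel_size = 0.1067,
                              n_frames_window = 500, upsampling = 10,
                              blur_sd = NULL) {
  if (upsampling < 1) stop("upsampling must be >= 1")
  sub <- locs[locs$frame < n_frames_window, , drop = FALSE]
  ps <- pixel_size / upsampling
  nc <- as.integer(ceiling(fov[1] / ps))
  nr <- as.integer(ceiling(fov[2] / ps))
  img <- matrix(0, nr, nc)
  if (nrow(sub) == 0) return(img)
  ci <- pmin(pmax(floor(sub$x_um / ps) + 1, 1), nc)
  ri <- pmin(pmax(floor(sub$y_um / ps) + 1, 1), nr)
  tab <- table(factor(ri, levels = seq_len(nr)),
               factor(ci, levels = seq_len(nc)))
  img <- matrix(as.numeric(tab), nr, nc)
  if (is.null(blur_sd)) {
    blur_sd <- if (!is.null(sub$precision_um))
      mean(sub$precision_um, na.rm = TRUE) else 0.02
  }
  sig_px <- blur_sd / ps
  if (sig_px > 0) {
    half <- ceiling(5 * sig_px)
    u <- (-half):half
    k1 <- stats::dnorm(u, sd = sig_px)
    kern <- k1 %o% k1
    kern <- kern / sum(kern)
    img <- EBImage::filter2(img, kern, boundary = 0)
  }
  img
}

#' Observable particle-density quality control
#'
#' Computes the mean per-frame localization density for each channel and
#' accepts the data set only if every channel stays below `max_density`,
#' the selection criterion for reliable single-molecule tracking.
#'
#' @param locs Localization data.frame with `frame` and optionally
#'   `channel`.
#' @param area Field-of-view area in um^2 (> 0).
#' @param n_frames Total number of acquired frames (frames without
#'   localizations count towards the average).
#' @param max_density Maximum tolerated mean density per um^2 (default 1).
#' @return List with `density` (named per channel), `accept` (logical) and
#'   `max_density`.
#' @export
density_qc <- function(locs, area, n_frames, max_density = 1) {
  if (!is.numeric(area) || area <= 0) stop("area must be > 0")
  ch <- if (!is.null(locs$channel)) locs$channel else rep("A", nrow(locs))
  dens <- tapply(rep(1, nrow(locs)), ch, sum) / (n_frames * area)
  if (nrow(locs) == 0) dens <- c(A = 0)
  list(density = dens,
       accept = all(dens < max_density),
       max_density = max_density)
}
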