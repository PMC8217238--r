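#' Normalize a FRAP bleach-ROI time series
#'
#' Per-cell scaling of the mean ROI fluorescence to
#' `(F(t) - F(0)) / (<F_pre> - F(0))`, where `F(0)` is the intensity at
#' the first post-bleach frame (which defines `t = 0`) and `<F_pre>` is
#' the mean over the pre-bleach frames.  A constant background offset
#' cancels in this linear transformation.  An optional acquisition-bleach
#' correction (from [bleach_correct()]) divides the raw series by the
#' fitted exponential decay before normalization.
#'
#' @param bleach Numeric vector of mean bleach-ROI intensities, pre-bleach
#'   frames first.
#' @param n_pre Number of pre-bleach frames (>= 1).
#' @param dt Frame interval in seconds.
#' @param correction Optional result of [bleach_correct()].
#' @return Object of class `frap_curve`: list with `time` (s, 0 at the
#'   first post-bleach frame), `value` (normalized, 0 at `t = 0` by
#'   construction), `f_pre`, `f0`, `bleach_depth` and
#'   `correction_rate` (`NA` if uncorrected).
#' @export
normalize_frap <- function(bleach, n_pre, dt = 0.5, correction = NULL) {
  if (n_pre < 1) stop("n_pre must be >= 1")
  if (length(bleach) <= n_pre) stop("post-bleach series is empty")
  k <- NA_real_
  if (!is.null(correction) && is.finite(correction$rate)) {
    k <- correction$rate
    t_acq <- (seq_along(bleach) - 1) * dt
    bleach <- bleach / exp(-k * t_acq)
  }
  f_pre <- mean(bleach[seq_len(n_pre)])
  post <- bleach[(n_pre + 1):length(bleach)]
  f0 <- post[1]
  if (f_pre == f0)
    stop("degenerate normalization: <F_pre> equals F(0)")
  structure(list(time = (seq_along(post) - 1) * dt,
                 value = (post - f0) / (f_pre - f0),
                 f_pre = f_pre, f0 = f0,
                 bleach_depth = 1 - f0 / f_pre,
                 correction_rate = k),
            class = "frap_curve")
}

#' Fit the acquisition-bleaching correction from control ROIs
#'
#' Fits a single exponential `A * exp(-k t)` to each control-ROI series
#' and averages the fitted parameters across cells; the averaged decay is
#' used to correct bleach-ROI series before normalization.  Series whose
#' fit fails to converge are dropped (and counted); if every series is
#' dropped no correction is returned, flagged by `rate = NA`.
#'
#' @param controls A numeric vector or list of numeric vectors (one
#'   control-ROI series per cell, each with at least 4 points).
#' @param dt Frame interval in seconds.
#' @return List with `rate` (averaged k, 1/s), `amplitude` (averaged A),
#'   `per_series` (data.frame of per-cell fits), `n_dropped`.
#' @export
bleach_correct <- function(controls, dt = 0.5) {
  if (is.numeric(controls)) controls <- list(controls)
  fits <- lapply(controls, function(v) {
    if (length(v) < 4) return(NULL)
    t <- (seq_along(v) - 1) * dt
    # log-linear start values, guarded against non-positive intensities
    vpos <- pmax(v, max(v) * 1e-6)
    k0 <- max(-stats::coef(stats::lm(log(vpos) ~ t))[2], 0)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = c(A = v[1], k = unname(k0)),
                         fn = function(p) v - p[1] * exp(-p[2] * t),
                         control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) NULL)
    if (is.null(fit) || fit$info %in% c(0, 9)) return(NULL)
    c(A = fit$par[1], k = fit$par[2])
  })
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok))
    return(list(rate = NA_real_, amplitude = NA_real_,
                per_series = NULL, n_dropped = length(controls)))
  m <- do.call(rbind, fits[ok])
  list(rate = mean(m[, 2]), amplitude = mean(m[, 1]),
       per_series = data.frame(amplitude = m[, 1], rate = m[, 2]),
       n_dropped = sum(!ok))
}

#' Bleach-depth quality control for a FRAP cell
#'
#' A cell is accepted only if at least `threshold` (default 40%) of its
#' pre-bleach intensity was removed by the single bleach step; shallower
#' bleaches (mis-centred spot, drift, low labeling) are excluded.  The
#' boundary is inclusive: a depth of exactly `threshold` is accepted.
#'
#' @param f_pre Pre-bleach mean intensity (> 0).
#' @param f0 Intensity at the first post-bleach frame.
#' @param threshold Required bleach depth as a fraction (default 0.40).
#' @return List with `depth` and `accept`.
#' @export
qc_bleach_depth <- function(f_pre, f0, threshold = 0.40) {
  if (!is.finite(f_pre) || !is.finite(f0) || f_pre <= 0)
    stop("invalid intensities for bleach-depth QC")
  depth <- 1 - f0 / f_pre
  list(depth = depth, accept = depth >= threshold)
}

#' Recovery metrics of a normalized FRAP curve
#'
#' @param curve A [normalize_frap()] result.
#' @param t_probe Readout time in seconds (default 48); the recovery at
#'   `t_probe` is linearly interpolated and reported as `NA` when the
#'   curve is shorter.
#' @param plateau_fraction Fraction of final points averaged for the
#'   plateau estimate (default 0.1).
#' @return List with `recovery_at_t_probe` and `plateau`.
#' @export
recovery_metrics <- function(curve, t_probe = 48, plateau_fraction = 0.1) {
  stopifnot(inherits(curve, "frap_curve"))
  rec <- if (max(curve$time) >= t_probe)
    stats::approx(curve$time, curve$value, xout = t_probe)$y
  else NA_real_
  n <- length(curve$value)
  tail_n <- max(1, ceiling(plateau_fraction * n))
  list(recovery_at_t_probe = rec,
       plateau = mean(curve$value[(n - tail_n + 1):n]))
}

#' End-to-end FRAP analysis of one cell
#'
#' Bleach correction (optional), bleach-depth QC and normalization,
#' returning the curve and its recovery metrics.
#'
#' @param bleach Bleach-ROI series (pre-bleach frames first).
#' @param controls Control-ROI series (vector or list) or `NULL` to skip
#'   the acquisition-bleach correction.
#' @param n_pre Number of pre-bleach frames.
#' @param dt Frame interval (s).
#' @param qc_threshold Bleach-depth threshold (default 0.40).
#' @param t_probe Readout time (s).
#' @return List with `curve`, `metrics`, `qc` (`NULL` curve/metrics when
#'   the cell is rejected).
#' @export
analyze_frap <- function(bleach, controls = NULL, n_pre, dt = 0.5,
                         qc_threshold = 0.40, t_probe = 48) {
  corr <- if (!is.null(controls)) bleach_correct(controls, dt) else NULL
  curve <- normalize_frap(bleach, n_pre, dt, correction = corr)
  qc <- qc_bleach_depth(curve$f_pre, curve$f0, qc_threshold)
  if (!qc$accept)
    return(list(curve = NULL, metrics = NULL, qc = qc))
  list(curve = curve, metrics = recovery_metrics(curve, t_probe), qc = qc)
}
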