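#' Calibrate the channel registration transform from bead localizations
#'
#' Least-squares affine fit mapping channel-B coordinates onto channel A
#' from matched multicolor bead localizations.  At least three
#' non-collinear bead pairs are required; the residual RMSE reports the
#' registration accuracy (sub-pixel for a valid calibration).
#'
#' @param beads_a,beads_b data.frames with `x_um`, `y_um` of the same
#'   beads localized in channels A and B (row-matched).
#' @return Object of class `channel_transform`: list with `matrix` (2 x 3
#'   affine, mapping `(x_b, y_b, 1)` to `(x_a, y_a)`), `rmse_um`,
#'   `n_beads`.
#' @export
calibrate_transform <- function(beads_a, beads_b) {
  if (nrow(beads_a) != nrow(beads_b))
    stop("bead tables must be row-matched")
  n <- nrow(beads_a)
  if (n < 3) stop("at least 3 bead pairs required")
  X <- cbind(beads_b$x_um, beads_b$y_um, 1)
  if (qr(X)$rank < 3) stop("beads are collinear; calibration impossible")
  Y <- cbind(beads_a$x_um, beads_a$y_um)
  B <- qr.solve(X, Y)                      # 3 x 2
  res <- Y - X %*% B
  structure(list(matrix = t(B), rmse_um = sqrt(mean(rowSums(res^2) / 2)),
                 n_beads = n),
            class = "channel_transform")
}

#' Apply a channel transform to coordinates
#'
#' @param transform A `channel_transform` (or `NULL` for identity).
#' @param x,y Channel-B coordinates in micrometers.
#' @return List with transformed `x`, `y` in channel-A coordinates.
#' @export
apply_transform <- function(transform, x, y) {
  if (is.null(transform)) return(list(x = x, y = y))
  M <- transform$matrix
  list(x = M[1, 1] * x + M[1, 2] * y + M[1, 3],
       y = M[2, 1] * x + M[2, 2] * y + M[2, 3])
}

#' Identify co-locomoting molecule pairs across two spectral channels
#'
#' Per frame, channel-B positions are mapped through the registration
#' transform and paired one-to-one with channel-A positions by optimal
#' assignment (minimum total distance) within the capture `radius`.  A
#' co-trajectory is a maximal run of at least `min_coframes` consecutive
#' frames in which the same two trajectories stay paired (any interruption
#' breaks the run).  The dual-labeled (co-locomoting) fraction is computed
#' per frame as the number of localizations belonging to an active
#' co-trajectory relative to all localizations of that frame, and reported
#' as its average over time.
#'
#' @param traj_a,traj_b Localization data.frames with `trajectory_id`,
#'   `frame`, `x_um`, `y_um` for channels A and B (from
#'   [link_trajectories()], or immobile-event centroid tracks).
#' @param transform Optional [calibrate_transform()] result mapping B onto
#'   A; `NULL` means the channels are already registered.
#' @param radius Capture radius in micrometers (default 0.150).
#' @param min_coframes Minimum number of consecutive co-localized frames
#'   (default 10, i.e. >= 320 ms at 32 ms/frame).
#' @return List with
#'   \describe{
#'     \item{cotrajectories}{data.frame `co_id`, `traj_a`, `traj_b`,
#'       `start_frame`, `end_frame`, `n_frames`, `mean_sep_um`.}
#'     \item{dual_fraction}{time-averaged fraction of localizations in
#'       co-trajectories (`NA` with a zero-localization input, flagged by
#'       `n = 0`).}
#'     \item{n}{total localization count across both channels.}
#'   }
#' @export
cotrack <- function(traj_a, traj_b, transform = NULL, radius = 0.150,
                    min_coframes = 10) {
  empty <- data.frame(co_id = integer(0), traj_a = integer(0),
                      traj_b = integer(0), start_frame = integer(0),
                      end_frame = integer(0), n_frames = integer(0),
                      mean_sep_um = numeric(0))
  ntot <- nrow(traj_a) + nrow(traj_b)
  if (nrow(traj_a) == 0 || nrow(traj_b) == 0)
    return(list(cotrajectories = empty,
                dual_fraction = if (ntot == 0) NA_real_ else 0,
                n = ntot))
  tb <- apply_transform(transform, traj_b$x_um, traj_b$y_um)
  b <- data.frame(frame = traj_b$frame, x = tb$x, y = tb$y,
                  id = traj_b$trajectory_id)
  a <- data.frame(frame = traj_a$frame, x = traj_a$x_um, y = traj_a$y_um,
                  id = traj_a$trajectory_id)
  a_by_f <- split(a, a$frame)
  b_by_f <- split(b, b$frame)
  common <- intersect(names(a_by_f), names(b_by_f))
  pair_rows <- vector("list", length(common))
  for (k in seq_along(common)) {
    af <- a_by_f[[common[k]]]; bf <- b_by_f[[common[k]]]
    pr <- cross_pairs_cpp(af$x, af$y, bf$x, bf$y, radius)
    if (!length(pr$i)) next
    match <- link_assign_cpp(nrow(af), nrow(bf), pr$i, pr$j,
                             pr$dist^2, rep(radius^2, nrow(af)))
    hit <- which(match > 0)
    if (!length(hit)) next
    # distances of the matched pairs
    d <- sqrt((af$x[hit] - bf$x[match[hit]])^2 +
              (af$y[hit] - bf$y[match[hit]])^2)
    pair_rows[[k]] <- data.frame(frame = af$frame[hit],
                                 traj_a = af$id[hit],
                                 traj_b = bf$id[match[hit]],
                                 sep = d)
  }
  pairs <- do.call(rbind, pair_rows[!vapply(pair_rows, is.null, logical(1))])
  if (is.null(pairs) || nrow(pairs) == 0)
    return(list(cotrajectories = empty, dual_fraction = 0, n = ntot))
  pairs <- pairs[order(pairs$traj_a, pairs$traj_b, pairs$frame), ]
  key <- paste(pairs$traj_a, pairs$traj_b)
  newrun <- c(TRUE, key[-1] != key[-nrow(pairs)] |
                diff(pairs$frame) != 1)
  runid <- cumsum(newrun)
  runlen <- tabulate(runid)
  keep_run <- which(runlen >= min_coframes)
  if (!length(keep_run))
    return(list(cotrajectories = empty, dual_fraction = 0, n = ntot))
  co <- pairs[runid %in% keep_run, ]
  co_runid <- match(runid[runid %in% keep_run], keep_run)
  cotraj <- data.frame(
    co_id = seq_along(keep_run),
    traj_a = tapply(co$traj_a, co_runid, `[`, 1),
    traj_b = tapply(co$traj_b, co_runid, `[`, 1),
    start_frame = as.integer(tapply(co$frame, co_runid, min)),
    end_frame = as.integer(tapply(co$frame, co_runid, max)),
    n_frames = as.integer(tapply(co$frame, co_runid, length)),
    mean_sep_um = as.numeric(tapply(co$sep, co_runid, mean)))

  # per-frame dual-labeled fraction: localizations in co-runs / all locs
  n_by_frame <- table(factor(c(a$frame, b$frame)))
  co_by_frame <- table(factor(co$frame, levels = names(n_by_frame))) * 2
  frac <- as.numeric(co_by_frame) / as.numeric(n_by_frame)
  list(cotrajectories = cotraj,
       dual_fraction = mean(frac),
       n = ntot)
}

#' Co-classify immobilization events across channels
#'
#' Immobile events from both channels are considered co-localized when
#' their centroids (after mapping channel B through the registration
#' transform) fall within the capture radius and their frame spans overlap
#' by at least `min_coframes` frames.
#'
#' @param events_a,events_b Event tables from [find_immobile()].
#' @inheritParams cotrack
#' @return data.frame `event_a`, `event_b`, `overlap_frames`,
#'   `separation_um`.
#' @export
cotrack_events <- function(events_a, events_b, transform = NULL,
                           radius = 0.150, min_coframes = 10) {
  empty <- data.frame(event_a = integer(0), event_b = integer(0),
                      overlap_frames = integer(0), separation_um = numeric(0))
  if (nrow(events_a) == 0 || nrow(events_b) == 0) return(empty)
  tb <- apply_transform(transform, events_b$centroid_x_um,
                        events_b$centroid_y_um)
  pr <- cross_pairs_cpp(events_a$centroid_x_um, events_a$centroid_y_um,
                        tb$x, tb$y, radius)
  if (!length(pr$i)) return(empty)
  ov <- pmin(events_a$end_frame[pr$i], events_b$end_frame[pr$j]) -
        pmax(events_a$start_frame[pr$i], events_b$start_frame[pr$j]) + 1L
  keep <- ov >= min_coframes
  data.frame(event_a = events_a$event_id[pr$i[keep]],
             event_b = events_b$event_id[pr$j[keep]],
             overlap_frames = ov[keep],
             separation_um = pr$dist[keep])
}
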