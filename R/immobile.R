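#' Identify transient immobilization events before tracking
#'
#' Density-based spatiotemporal clustering of localizations: a cluster
#' grows frame by frame while a localization in the next frame (allowing up
#' to `max_gap` missing frames) lies within `eps_radius` of the cluster's
#' running centroid, which is updated incrementally.  Clusters whose
#' temporal extent exceeds `min_frames` frames are reported as
#' immobilization events and their member localizations are flagged
#' immobile; events must also contain more than `min_frames` member
#' localizations, so sparse chance clusters bridged by the gap allowance
#' do not qualify.  The per-frame immobile fraction (immobile / all
#' localizations of that frame) is reported as its average over time.
#' Every localization belongs to at most one event; the greedy temporal
#' sweep resolves overlaps in favour of the earlier-started cluster.
#'
#' @param locs Localization data.frame from one channel with columns
#'   `frame` (0-based), `x_um`, `y_um`.
#' @param eps_radius Search radius around the running centroid in
#'   micrometers (default 0.120).
#' @param min_frames Minimum temporal extent in frames an event must
#'   exceed (default 20, i.e. > 640 ms at 32 ms/frame).
#' @param max_gap Maximum number of consecutive missing frames inside an
#'   event (default 3, mirroring the tracking gap allowance).
#' @return List with
#'   \describe{
#'     \item{events}{data.frame `event_id`, `centroid_x_um`,
#'       `centroid_y_um`, `start_frame`, `end_frame`, `n_localizations`.}
#'     \item{immobile_fraction}{time-averaged immobile fraction (`NA` when
#'       there are no localizations).}
#'     \item{localizations}{the input with a logical `immobile` column.}
#'     \item{mobile}{the mobile subset (complement of event members).}
#'   }
#' @export
find_immobile <- function(locs, eps_radius = 0.120, min_frames = 20,
                          max_gap = 3) {
  n <- nrow(locs)
  empty_events <- data.frame(event_id = integer(0),
                             centroid_x_um = numeric(0),
                             centroid_y_um = numeric(0),
                             start_frame = integer(0),
                             end_frame = integer(0),
                             n_localizations = integer(0))
  if (n == 0) {
    locs$immobile <- logical(0)
    return(list(events = empty_events, immobile_fraction = NA_real_,
                localizations = locs, mobile = locs))
  }
  ord <- order(locs$frame)
  x <- locs$x_um[ord]; y <- locs$y_um[ord]; fr <- locs$frame[ord]
  frames <- sort(unique(fr))
  idx_by_frame <- split(seq_len(n), fr)

  # cluster state, preallocated and grown as needed
  cap <- 256L
  cl_x <- numeric(cap); cl_y <- numeric(cap)   # running centroid
  cl_n <- integer(cap); cl_start <- integer(cap); cl_last <- integer(cap)
  cl_open <- logical(cap)
  n_cl <- 0L
  assign_cl <- integer(n)                      # cluster id per localization

  grow <- function() {
    cap2 <- cap * 2L
    length(cl_x) <<- cap2; length(cl_y) <<- cap2
    length(cl_n) <<- cap2; length(cl_start) <<- cap2
    length(cl_last) <<- cap2
    cl_open <<- c(cl_open, logical(cap))
    cap <<- cap2
  }

  for (f in frames) {
    ii <- idx_by_frame[[as.character(f)]]
    open <- which(cl_open[seq_len(n_cl)])
    # close clusters that have been silent for more than max_gap frames
    stale <- open[f - cl_last[open] > max_gap + 1L]
    cl_open[stale] <- FALSE
    open <- open[f - cl_last[open] <= max_gap + 1L]
    taken <- logical(length(ii))
    if (length(open)) {
      pr <- cross_pairs_cpp(cl_x[open], cl_y[open],
                            x[ii], y[ii], eps_radius)
      if (length(pr$i)) {
        o <- order(pr$dist)
        used_cl <- logical(length(open))
        for (k in o) {
          a <- pr$i[k]; b <- pr$j[k]
          if (used_cl[a] || taken[b]) next
          used_cl[a] <- TRUE; taken[b] <- TRUE
          ci <- open[a]; li <- ii[b]
          assign_cl[li] <- ci
          cl_n[ci] <- cl_n[ci] + 1L
          cl_x[ci] <- cl_x[ci] + (x[li] - cl_x[ci]) / cl_n[ci]
          cl_y[ci] <- cl_y[ci] + (y[li] - cl_y[ci]) / cl_n[ci]
          cl_last[ci] <- f
        }
      }
    }
    # unassigned localizations seed new clusters
    for (b in which(!taken)) {
      li <- ii[b]
      n_cl <- n_cl + 1L
      if (n_cl > cap) grow()
      cl_x[n_cl] <- x[li]; cl_y[n_cl] <- y[li]
      cl_n[n_cl] <- 1L; cl_start[n_cl] <- f; cl_last[n_cl] <- f
      cl_open[n_cl] <- TRUE
      assign_cl[li] <- n_cl
    }
  }

  span <- cl_last[seq_len(n_cl)] - cl_start[seq_len(n_cl)] + 1L
  # a genuine immobilization yields ~one member per frame; requiring the
  # member count as well as the span to exceed min_frames rejects sparse
  # chance clusters kept alive by the gap allowance
  valid <- which(span > min_frames & cl_n[seq_len(n_cl)] > min_frames)
  immobile_sorted <- assign_cl %in% valid
  events <- if (length(valid)) {
    data.frame(event_id = seq_along(valid),
               centroid_x_um = cl_x[valid],
               centroid_y_um = cl_y[valid],
               start_frame = cl_start[valid],
               end_frame = cl_last[valid],
               n_localizations = cl_n[valid])
  } else empty_events

  immobile <- logical(n)
  immobile[ord] <- immobile_sorted
  out <- locs
  out$immobile <- immobile
  frac_by_frame <- tapply(immobile_sorted, fr, mean)
  list(events = events,
       immobile_fraction = mean(frac_by_frame),
       localizations = out,
       mobile = out[!immobile, setdiff(names(out), "immobile"),
                    drop = FALSE])
}
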