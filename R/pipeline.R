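#' Run the single-molecule analysis pipeline on a simulated scenario
#'
#' Executes simulate -> density QC -> immobile clustering -> trajectory
#' linking -> MSD diffusion fitting -> dual-color co-tracking ->
#' confinement analysis (any prefix selectable via `stages`) and returns
#' all stage outputs plus a flat summary.  With an `out_dir`, the
#' localization/trajectory/co-trajectory tables are written as CSV and the
#' summary as JSON, together with a parameter echo that suffices to re-run
#' the result.  The pipeline is deterministic given the scenario seed.
#'
#' @param scenario A [sim_scenario()].
#' @param stages Character vector of stages to run, a prefix of
#'   `c("simulate", "qc", "cluster", "track", "cotrack", "confine")`.
#' @param params Named list overriding analysis defaults:
#'   `max_density`, `eps_radius_um`, `min_frames`, `max_gap`,
#'   `gate_factor`, `d_init_um2_s`, `cotrack_radius_um`, `min_coframes`,
#'   `confine_window`, `alpha_conf`, `d_null_um2_s`, `min_arrest_frames`.
#' @param out_dir Optional output directory for CSV/JSON artifacts.
#' @return List with per-stage results (`sim`, `qc`, `immobile` per
#'   channel, `tracks`, `diffusion`, `cotracking`, `confinement`),
#'   `summary` (named list of headline numbers), and `status`
#'   (`"ok"` or `"qc_failed"`; on QC failure later stages are skipped and
#'   partial outputs retained).
#' @export
run_pipeline <- function(scenario,
                         stages = c("simulate", "qc", "cluster", "track",
                                    "cotrack", "confine"),
                         params = list(), out_dir = NULL) {
  all_stages <- c("simulate", "qc", "cluster", "track", "cotrack",
                  "confine")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  p <- utils::modifyList(list(
    max_density = 1, eps_radius_um = 0.120, min_frames = 20, max_gap = 3,
    gate_factor = 3, d_init_um2_s = 0.5, cotrack_radius_um = 0.150,
    min_coframes = 10, confine_window = 10, alpha_conf = 1e-3,
    d_null_um2_s = 0.19, min_arrest_frames = 10), params)
  dt <- scenario$frame_interval
  out <- list(status = "ok", params = p, seed = scenario$seed)
  summary <- list(seed = scenario$seed)

  sim <- simulate_trajectories(scenario)
  out$sim <- sim
  locs <- sim$localizations
  summary$n_localizations <- nrow(locs)

  if ("qc" %in% stages) {
    qc <- density_qc(locs, prod(scenario$fov), scenario$n_frames,
                     p$max_density)
    out$qc <- qc
    summary$density_per_um2 <- as.list(qc$density)
    if (!qc$accept) {
      out$status <- "qc_failed"
      out$summary <- summary
      if (!is.null(out_dir)) write_pipeline_artifacts(out, out_dir)
      return(out)
    }
  }

  channels <- sort(unique(locs$channel))
  if ("cluster" %in% stages) {
    out$immobile <- lapply(stats::setNames(channels, channels), function(ch)
      find_immobile(locs[locs$channel == ch, ], p$eps_radius_um,
                    p$min_frames, p$max_gap))
    summary$immobile_fraction <- lapply(out$immobile, `[[`,
                                        "immobile_fraction")
  }

  if ("track" %in% stages) {
    mob <- if (!is.null(out$immobile))
      lapply(out$immobile, `[[`, "mobile")
    else
      lapply(stats::setNames(channels, channels), function(ch)
        locs[locs$channel == ch, ])
    out$tracks <- lapply(mob, link_trajectories, frame_interval = dt,
                         max_gap = p$max_gap, gate_factor = p$gate_factor,
                         d_init = p$d_init_um2_s)
    out$diffusion <- lapply(out$tracks, fit_trajectories,
                            frame_interval = dt)
    summary$median_D_um2_s <- lapply(out$diffusion, function(d)
      d$summary$median_D)
  }

  if ("cotrack" %in% stages && all(c("A", "B") %in% channels)) {
    ct <- cotrack(out$tracks[["A"]], out$tracks[["B"]],
                  transform = NULL, radius = p$cotrack_radius_um,
                  min_coframes = p$min_coframes)
    out$cotracking <- ct
    summary$dual_fraction_mobile <- ct$dual_fraction
    if (!is.null(out$immobile)) {
      ce <- cotrack_events(out$immobile[["A"]]$events,
                           out$immobile[["B"]]$events,
                           radius = p$cotrack_radius_um,
                           min_coframes = p$min_coframes)
      out$coevents <- ce
      summary$n_colocalized_immobile_events <- nrow(ce)
      # total co-localized fraction (mobile co-runs + co-classified
      # immobile events) relative to all localizations, the quantity whose
      # correlation with the immobile fraction characterises
      # oligomerization-driven arrest
      n_imm <- sum(vapply(out$immobile, function(x)
        sum(x$localizations$immobile), numeric(1)))
      n_mob <- ct$n
      co_imm_locs <- 2 * sum(ce$overlap_frames)
      dual_mob <- if (is.na(ct$dual_fraction)) 0 else ct$dual_fraction
      summary$dual_fraction_total <-
        (dual_mob * n_mob + co_imm_locs) / max(n_mob + n_imm, 1)
    }
  }

  if ("confine" %in% stages && !is.null(out$tracks)) {
    ch <- channels[1]
    out$confinement <- analyze_confinement(
      out$tracks[[ch]], window = p$confine_window,
      d_null = p$d_null_um2_s, dt = dt, alpha_conf = p$alpha_conf,
      min_arrest_frames = p$min_arrest_frames,
      epsilon = scenario$loc_noise_sigma, seed = scenario$seed)
    summary$confined_fraction <- out$confinement$confined_fraction
    summary$p_arrest <- out$confinement$transitions$p_arrest
    summary$p_release <- out$confinement$transitions$p_release
    summary$domain_diameter_nm <-
      if (is.na(out$confinement$domain$diameter_um)) NA_real_
      else out$confinement$domain$diameter_um * 1000
  }

  out$summary <- summary
  if (!is.null(out_dir)) write_pipeline_artifacts(out, out_dir)
  out
}

write_pipeline_artifacts <- function(out, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_localizations(out$sim$localizations,
                      file.path(out_dir, "localizations.csv"))
  if (!is.null(out$tracks))
    for (ch in names(out$tracks))
      write_localizations(out$tracks[[ch]],
                          file.path(out_dir,
                                    sprintf("trajectories_%s.csv", ch)))
  if (!is.null(out$immobile))
    for (ch in names(out$immobile))
      if (nrow(out$immobile[[ch]]$events))
        utils::write.csv(out$immobile[[ch]]$events,
                         file.path(out_dir,
                                   sprintf("immobile_events_%s.csv", ch)),
                         row.names = FALSE)
  if (!is.null(out$cotracking) && nrow(out$cotracking$cotrajectories))
    utils::write.csv(out$cotracking$cotrajectories,
                     file.path(out_dir, "cotrajectories.csv"),
                     row.names = FALSE)
  write_summary(out$summary, file.path(out_dir, "summary.json"))
  invisible(out_dir)
}
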