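#' Trapping model for transient nanodomain arrest
#'
#' Two-state (mobile/arrested) switching kinetics with confinement of the
#' arrested state inside a circular nanodomain.  On every frame a mobile
#' complex becomes arrested with probability `p_arrest`; an arrested complex
#' is released with probability `p_release`.  While arrested, the complex
#' performs residual diffusion with coefficient `d_trap` confined to a disc
#' of diameter `domain_diameter` centred at the position where the arrest
#' started.
#'
#' @param p_arrest Per-frame probability of the mobile to arrested
#'   transition, in `[0, 1]`.
#' @param p_release Per-frame probability of the arrested to mobile
#'   transition, in `[0, 1]`.
#' @param domain_diameter Diameter of the trapping nanodomain in micrometers.
#'   Default 0.035 (35 nm), typical of the nanoscopic membrane domains that
#'   transiently trap receptors.
#' @param d_trap Residual diffusion coefficient inside the domain in
#'   um^2/s.  Must be non-negative.
#' @return An object of class `trap_model`.
#' @export
trap_model <- function(p_arrest = 0, p_release = 0,
                       domain_diameter = 0.035, d_trap = 0.01) {
  stopifnot(is.finite(p_arrest), is.finite(p_release),
            is.finite(domain_diameter), is.finite(d_trap))
  if (p_arrest < 0 || p_arrest > 1 || p_release < 0 || p_release > 1)
    stop("transition probabilities must lie in [0, 1]")
  if (domain_diameter <= 0) stop("domain_diameter must be > 0")
  if (d_trap < 0) stop("d_trap must be >= 0")
  structure(list(p_arrest = p_arrest, p_release = p_release,
                 domain_diameter = domain_diameter, d_trap = d_trap),
            class = "trap_model")
}

#' Simulation scenario for synthetic single-molecule experiments
#'
#' Bundles all parameters of the ground-truth generator: free diffusion,
#' frame timing, field of view, observable particle density, oligomer size
#' distribution, stochastic two-color sub-unit labeling, nanodomain trapping
#' and localization noise.  Defaults reproduce the imaging conditions the
#' analysis is designed for: membrane receptors diffusing at 0.19 um^2/s
#' imaged at 32 ms/frame over 2000 frames with ~20 nm localization
#' precision and an observable particle density below 1 per um^2.
#'
#' @param d_free Free diffusion coefficient in um^2/s.
#' @param frame_interval Frame interval in seconds.
#' @param n_frames Number of frames (>= 2).
#' @param fov Numeric length-2, field of view (x, y) in micrometers.
#' @param boundary One of `"periodic"`, `"reflecting"`, `"none"`.
#' @param density Expected observable (labeled) particle density summed over
#'   both channels, per um^2.
#' @param oligomer_size_dist Named numeric vector of probabilities over
#'   complex sizes; names are the sizes (n >= 1).  Default: all monomers.
#' @param p_label Per-subunit labeling probability in `[0, 1]`.
#' @param color_split Fraction of labels assigned to channel A (vs B).
#' @param trap A [trap_model()].
#' @param loc_noise_sigma Per-axis localization error (standard deviation)
#'   in micrometers added to the true positions of each labeled emitter.
#' @param seed Integer seed; the generator is bit-reproducible given the
#'   seed.
#' @param max_particles Cap on the expected number of simulated complexes;
#'   scenarios whose density implies more are rejected.
#' @return An object of class `sim_scenario`.
#' @seealso [simulate_trajectories()]
#' @export
sim_scenario <- function(d_free = 0.19, frame_interval = 0.032,
                         n_frames = 2000, fov = c(30, 30),
                         boundary = c("periodic", "reflecting", "none"),
                         density = 0.9,
                         oligomer_size_dist = c("1" = 1),
                         p_label = 0.08, color_split = 0.5,
                         trap = trap_model(),
                         loc_noise_sigma = 0.020,
                         seed = 1L,
                         max_particles = 20000) {
  boundary <- match.arg(boundary)
  stopifnot(is.numeric(fov), length(fov) == 2, all(fov > 0))
  if (!is.finite(d_free) || d_free < 0) stop("d_free must be >= 0")
  if (p_label < 0 || p_label > 1) stop("p_label must lie in [0, 1]")
  if (color_split < 0 || color_split > 1)
    stop("color_split must lie in [0, 1]")
  if (!is.finite(density) || density <= 0) stop("density must be > 0")
  if (n_frames < 2) stop("n_frames must be >= 2")
  if (!inherits(trap, "trap_model")) stop("trap must be a trap_model")
  if (loc_noise_sigma < 0) stop("loc_noise_sigma must be >= 0")
  sizes <- as.integer(names(oligomer_size_dist))
  if (any(is.na(sizes)) || any(sizes < 1))
    stop("oligomer_size_dist must be named by integer sizes >= 1")
  p <- oligomer_size_dist / sum(oligomer_size_dist)
  mean_size <- sum(sizes * p)
  # expected labeled emitters per complex; density counts observable emitters
  exp_labels <- mean_size * p_label
  if (exp_labels <= 0) stop("p_label and oligomer sizes imply no observable particles")
  n_complexes <- max(1L, as.integer(round(density * prod(fov) / exp_labels)))
  if (n_complexes > max_particles)
    stop(sprintf(paste0("scenario implies %d complexes, above the cap of %d; ",
                        "reduce density or raise max_particles"),
                 n_complexes, max_particles))
  structure(list(d_free = d_free, frame_interval = frame_interval,
                 n_frames = as.integer(n_frames), fov = fov,
                 boundary = boundary, density = density,
                 oligomer_size_dist = stats::setNames(as.numeric(p), sizes),
                 p_label = p_label, color_split = color_split,
                 trap = trap, loc_noise_sigma = loc_noise_sigma,
                 seed = as.integer(seed), n_complexes = n_complexes),
            class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat("Simulation scenario:\n")
  cat(sprintf("  D_free %.3g um^2/s, dt %.3g s, %d frames, FOV %g x %g um (%s)\n",
              x$d_free, x$frame_interval, x$n_frames, x$fov[1], x$fov[2],
              x$boundary))
  cat(sprintf("  density %.3g /um^2 -> %d complexes; p_label %.3g, split %.2f\n",
              x$density, x$n_complexes, x$p_label, x$color_split))
  cat(sprintf("  trap: p_arrest %.3g, p_release %.3g, domain %.3g um, d_trap %.3g\n",
              x$trap$p_arrest, x$trap$p_release, x$trap$domain_diameter,
              x$trap$d_trap))
  cat(sprintf("  loc noise %.3g um, seed %d\n", x$loc_noise_sigma, x$seed))
  invisible(x)
}
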