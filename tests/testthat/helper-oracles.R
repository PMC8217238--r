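# Independent oracles used across the suite.

# Brute-force enumeration of the dual-labeled probability: each subunit is
# unlabeled / labeled-A / labeled-B with probabilities (1-p, p*s, p*(1-s));
# sum the probability of all 3^n states with >= 1 A and >= 1 B.
enumerate_dual_fraction <- function(n, p_label, color_split) {
  states <- expand.grid(rep(list(0:2), n))  # 0 none, 1 A, 2 B
  pr <- c(1 - p_label, p_label * color_split, p_label * (1 - color_split))
  probs <- apply(states, 1, function(s) prod(pr[s + 1]))
  dual <- apply(states, 1, function(s) any(s == 1) && any(s == 2))
  sum(probs[dual])
}

# iid uniform points in a disc of given diameter
uniform_disc <- function(n, diameter) {
  r <- diameter / 2 * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  data.frame(x_um = r * cos(th), y_um = r * sin(th))
}

# a free-monomer scenario where every particle is observable in channel A
free_scenario <- function(n_frames, fov, density, seed,
                          d_free = 0.19, eps = 0.020,
                          boundary = "none", trap = trap_model()) {
  sim_scenario(d_free = d_free, frame_interval = 0.032,
               n_frames = n_frames, fov = fov, boundary = boundary,
               density = density, p_label = 1, color_split = 1,
               trap = trap, loc_noise_sigma = eps, seed = seed)
}

# attach ground-truth state to each observed localization
truth_states <- function(sim) {
  pos <- sim$truth$positions
  key <- paste(sim$localizations$frame, sim$localizations$complex_id)
  pos$state[match(key, paste(pos$frame, pos$complex_id))]
}

# cut a localization table into maximal runs where flag is TRUE
cut_segments <- function(df, flag) {
  r <- rle(as.logical(flag))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  lapply(which(r$values), function(k) df[starts[k]:ends[k], , drop = FALSE])
}
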