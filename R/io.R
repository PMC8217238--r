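#' Single-channel image time series
#'
#' Container for one spectral channel of a fluorescence movie: a 3D array
#' of non-negative counts indexed (frame, row, col), with pixel size and
#' frame interval metadata.
#'
#' @param pixels 3D numeric array `(frame, row, col)` of non-negative
#'   counts.
#' @param pixel_size Pixel size in micrometers (> 0).
#' @param frame_interval Frame interval in seconds (> 0).
#' @param channel Channel label, e.g. `"A"`.
#' @return Object of class `frame_stack`.
#' @export
frame_stack <- function(pixels, pixel_size, frame_interval, channel = "A") {
  stopifnot(is.array(pixels), length(dim(pixels)) == 3)
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be > 0")
  if (!is.numeric(frame_interval) || frame_interval <= 0)
    stop("frame_interval must be > 0")
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 frame_interval = frame_interval, channel = channel),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("frame_stack: %d frames of %d x %d px, %.4g um/px, %.4g s/frame, channel %s\n",
              d[1], d[2], d[3], x$pixel_size, x$frame_interval, x$channel))
  invisible(x)
}

#' Read a multi-page TIFF stack
#'
#' Loads a single-channel movie from a multi-page TIFF.  Pixel size and
#' frame interval are not reliably stored in TIFF tags, so they must be
#' supplied (typically from the run configuration).
#'
#' @param path Path to a multi-page TIFF file.
#' @param pixel_size Pixel size in micrometers; required.
#' @param frame_interval Frame interval in seconds; required.
#' @param channel Channel label.
#' @return A [frame_stack()].
#' @export
read_stack <- function(path, pixel_size = NULL, frame_interval = NULL,
                       channel = "A") {
  if (is.null(pixel_size))
    stop("pixel_size is not stored in TIFF tags; supply it explicitly ",
         "(e.g. from the run config, key pixel_size_um)")
  if (is.null(frame_interval))
    stop("frame_interval is required; supply it explicitly ",
         "(e.g. from the run config, key frame_interval_s)")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- vapply(pages, function(p) dim(p)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("mixed page sizes in ", path)
  px <- array(0, dim = c(length(pages), dims[1, 1], dims[2, 1]))
  for (i in seq_along(pages)) px[i, , ] <- pages[[i]]
  frame_stack(px, pixel_size, frame_interval, channel)
}

#' Write a frame stack as 16-bit multi-page TIFF
#'
#' @param stack A [frame_stack()]; pixel values must be integers in
#'   `[0, 65535]` (counts are rounded).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  px <- round(stack$pixels)
  px[px < 0] <- 0
  if (max(px) > 65535)
    stop("pixel counts exceed the 16-bit range")
  pages <- lapply(seq_len(dim(px)[1]), function(f)
    px[f, , ] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write/read localization tables as CSV
#'
#' The interchange schema is a plain CSV with header; the canonical columns
#' are `frame`, `x_um`, `y_um` plus whatever the producing stage adds
#' (`precision_um`, `intensity`, `background`, `channel`, `trajectory_id`,
#' `immobile`, ...).
#'
#' @param locs data.frame of localizations.
#' @param path File path.
#' @return `read_localizations` returns the data.frame;
#'   `write_localizations` returns `path` invisibly.
#' @export
write_localizations <- function(locs, path) {
  utils::write.csv(locs, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_localizations
#' @export
read_localizations <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

run_config_keys <- c(
  "seed", "out_dir", "pixel_size_um", "frame_interval_s", "psf_sigma_um",
  "alpha_det", "box", "max_density", "eps_radius_um", "min_frames",
  "max_gap", "gate_factor", "d_init_um2_s", "msd_max_lag",
  "cotrack_radius_um", "min_coframes", "confine_window", "alpha_conf",
  "d_null_um2_s", "min_arrest_frames", "stages", "scenario", "frap")

#' Read and validate a pipeline run configuration (YAML)
#'
#' Unknown top-level keys are rejected so that typos fail loudly rather
#' than silently using defaults.
#'
#' @param path Path to a YAML config file.
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), run_config_keys)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg
}

#' Write a summary list as JSON
#'
#' @param x Named list of summary quantities.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
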