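#' Simulation configuration
#'
#' Builds and validates the configuration for the synthetic time-lapse +
#' endpoint-IF generator. Defaults encode the study conditions the analysis
#' is benchmarked under: imaging every 12 minutes for 24 hours, and a
#' population composition in which 79.0% of cells enter the CDK2-increasing
#' state after mitosis, 8.8% stay CDK2-low, 7.8% emerge from a transient
#' CDK2-low state, 2.3% remain in prolonged quiescence without dividing and
#' 2.1% build up CDK2 activity without dividing.
#'
#' @param n_cells number of cells present at the first frame.
#' @param composition named fractions over the five fate classes
#'   (`CDK2inc`, `CDK2low`, `CDK2emerge`, `prolonged_quiescent`,
#'   `nondividing_emerge`); must be nonnegative and sum to 1.
#' @param frame_interval minutes between frames.
#' @param duration movie length in hours.
#' @param pixel_size microns per pixel.
#' @param field_shape integer `c(rows, cols)`, or `NULL` to size the field
#'   automatically for a subconfluent density at `n_cells`.
#' @param nucleus_radius nucleus radius in microns.
#' @param noise_sd Gaussian pixel noise, intensity units.
#' @param background_level constant background, intensity units.
#' @param jitter_shift integer `c(dy, dx)` applied to the endpoint IF
#'   images, or `"random"` to draw one uniformly within `jitter_radius`.
#' @param jitter_radius maximum |shift| per axis when `jitter_shift` is
#'   `"random"`.
#' @param seed integer seed; every stochastic output of the generator is a
#'   deterministic function of the configuration including this seed.
#' @param h2b_mass_mean,h2b_mass_cv mean and coefficient of variation of the
#'   per-cell integrated H2B fluorescence ("mass").
#' @param sensor_mass total sensor fluorescence per cell, split between
#'   nucleus and perinuclear cytoplasm according to the cell's CDK2 activity.
#' @param trace_noise_sd frame-to-frame biological fluctuation of the true
#'   activity ratio.
#' @param if_noise_sdlog lognormal measurement noise on endpoint IF values.
#' @param motion_sd random-walk step (pixels/frame) of nucleus centers.
#' @param cyto_width width in pixels of the rendered cytoplasmic annulus.
#' @param contact_gap minimum gap (pixels) between nucleus edges enforced
#'   by the motion model (nuclei may touch but not interpenetrate).
#' @param crowding scales the minimum separation between seeded nuclei;
#'   values < 1 increase the frequency of touching nuclei.
#' @param s_phase_window hours post-anaphase during which cycling cells
#'   incorporate EdU.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_cells = 200,
                       composition = c(CDK2inc = 0.790, CDK2low = 0.088,
                                       CDK2emerge = 0.078,
                                       prolonged_quiescent = 0.023,
                                       nondividing_emerge = 0.021),
                       frame_interval = 12,
                       duration = 24,
                       pixel_size = 1,
                       field_shape = NULL,
                       nucleus_radius = 5,
                       noise_sd = 5,
                       background_level = 100,
                       jitter_shift = "random",
                       jitter_radius = 8,
                       seed = 1,
                       h2b_mass_mean = 30000,
                       h2b_mass_cv = 0.10,
                       sensor_mass = 265000,
                       trace_noise_sd = 0.02,
                       if_noise_sdlog = 0.10,
                       motion_sd = 0.3,
                       cyto_width = 7,
                       contact_gap = 3,
                       crowding = 1,
                       s_phase_window = c(5, 13)) {
  fates <- c("CDK2inc", "CDK2low", "CDK2emerge", "prolonged_quiescent",
             "nondividing_emerge")
  comp <- rep(0, 5); names(comp) <- fates
  if (is.null(names(composition)) && length(composition) == 5) {
    names(composition) <- fates
  }
  if (!all(names(composition) %in% fates)) {
    stop("unknown fate names in composition: ",
         paste(setdiff(names(composition), fates), collapse = ", "))
  }
  comp[names(composition)] <- composition
  if (any(comp < 0)) stop("composition fractions must be nonnegative")
  if (abs(sum(comp) - 1) > 1e-9) stop("composition fractions must sum to 1")
  if (pixel_size <= 0) stop("pixel_size must be positive")
  n_steps <- duration * 60 / frame_interval
  if (abs(n_steps - round(n_steps)) > 1e-9 || n_steps < 1) {
    stop("duration/frame_interval must yield an integer frame count >= 2")
  }
  if (n_cells < 1) stop("n_cells must be >= 1")
  if (duration < 16 &&
      sum(comp[c("CDK2inc", "CDK2low", "CDK2emerge",
                 "nondividing_emerge")]) > 0) {
    stop("duration must be >= 16 h for dividing or emerging fates to be observable")
  }
  r_px <- nucleus_radius / pixel_size
  if (is.null(field_shape)) {
    # ~1800 px^2 of field per seeded cell keeps the culture subconfluent
    # even after divisions nearly double the cell count.
    side <- ceiling(sqrt(n_cells * 1800 * (r_px / 5)^2))
    field_shape <- c(side, side)
  }
  field_shape <- as.integer(field_shape)
  cfg <- list(n_cells = as.integer(n_cells), composition = comp,
              frame_interval = frame_interval, duration = duration,
              pixel_size = pixel_size, field_shape = field_shape,
              nucleus_radius = nucleus_radius, noise_sd = noise_sd,
              background_level = background_level,
              jitter_shift = jitter_shift, jitter_radius = jitter_radius,
              seed = as.integer(seed),
              h2b_mass_mean = h2b_mass_mean, h2b_mass_cv = h2b_mass_cv,
              sensor_mass = sensor_mass, trace_noise_sd = trace_noise_sd,
              if_noise_sdlog = if_noise_sdlog, motion_sd = motion_sd,
              cyto_width = cyto_width, contact_gap = contact_gap,
              crowding = crowding,
              s_phase_window = s_phase_window,
              n_frames = as.integer(round(n_steps)) + 1L,
              r_px = r_px)
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  %d cells, %d frames (%g min interval, %g h), field %d x %d px\n",
              x$n_cells, x$n_frames, x$frame_interval, x$duration,
              x$field_shape[1], x$field_shape[2]))
  cat("  composition:",
      paste(sprintf("%s=%.3f", names(x$composition), x$composition),
            collapse = " "), "\n")
  invisible(x)
}

# Hour stamps of the movie frames.
frame_times <- function(config) {
  seq(0, config$duration, by = config$frame_interval / 60)
}
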