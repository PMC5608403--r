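# Rendering synthetic movies and endpoint IF images from a ground-truth
# cohort. Nuclei are uniform disks whose integrated H2B intensity equals the
# cell's H2B mass; the sensor channel splits a fixed total sensor mass
# between the nucleus and a perinuclear cytoplasmic annulus so that the
# ratio of (cytoplasm mean)/(nuclear mean) equals the cell's true activity.

# Render per-cell nuclear/cytoplasmic channel values into field images.
# Nuclei are disks; contested cytoplasm pixels belong to the cell with the
# nearest nucleus edge and never overlap a nucleus (territorial monolayer).
render_values <- function(cohort, frame, nuc_vals, cyto_vals, alive) {
  config <- cohort$config
  shape <- config$field_shape
  imgs <- render_channels_cpp(cohort$pos_row[alive, frame],
                              cohort$pos_col[alive, frame],
                              cohort$cells$radius[alive], config$cyto_width,
                              shape[1], shape[2],
                              as.matrix(nuc_vals), as.matrix(cyto_vals),
                              config$background_level)
  names(imgs) <- colnames(nuc_vals)
  imgs
}

# Nucleus and owned-cytoplasm pixel counts for the cells alive at `frame`.
frame_areas <- function(cohort, frame, alive) {
  config <- cohort$config
  cell_areas_cpp(cohort$pos_row[alive, frame], cohort$pos_col[alive, frame],
                 cohort$cells$radius[alive], config$cyto_width,
                 config$field_shape[1], config$field_shape[2])
}

derived_seed <- function(seed, salt) {
  as.integer((as.numeric(seed) * 7919 + salt) %% 2147483647)
}

#' Render one frame of the synthetic movie
#'
#' @param cohort a [simulate_cohort()] result.
#' @param frame frame index (1-based).
#' @param noise add Gaussian pixel noise of `config$noise_sd`? The noise
#'   stream is a deterministic function of the configuration seed and the
#'   frame index, so frames can be rendered in any order.
#' @return list with matrices `h2b` and `sensor`.
#' @export
render_frame <- function(cohort, frame, noise = TRUE) {
  config <- cohort$config
  alive <- which(cohort$cells$birth_frame <= frame &
                   cohort$cells$end_frame >= frame)
  ar <- frame_areas(cohort, frame, alive)
  act <- pmax(0.05, cohort$activity[alive, frame])
  n_v <- config$sensor_mass / (ar$a_n + act * ar$a_c)
  nuc_vals <- cbind(h2b = cohort$cells$h2b_mass[alive] / pmax(1L, ar$a_n),
                    sensor = n_v)
  cyto_vals <- cbind(h2b = 0, sensor = act * n_v)
  imgs <- render_values(cohort, frame, nuc_vals, cyto_vals, alive)
  h2b <- imgs$h2b; sensor <- imgs$sensor
  if (noise && config$noise_sd > 0) {
    nz <- with_seed(derived_seed(config$seed, frame), {
      list(h = stats::rnorm(length(h2b), 0, config$noise_sd),
           s = stats::rnorm(length(sensor), 0, config$noise_sd))
    })
    h2b <- h2b + nz$h; sensor <- sensor + nz$s
    h2b[h2b < 0] <- 0; sensor[sensor < 0] <- 0
  }
  list(h2b = h2b, sensor = sensor)
}

#' Render the full synthetic movie
#'
#' Materializes every frame (see [render_frame()] for the construction).
#' For large fields prefer streaming frame-by-frame via [render_frame()],
#' as [analyze_movie()] does.
#'
#' @inheritParams render_frame
#' @param frames frame indices to render (default all).
#' @return An object of class `image_stack`: list with `h2b` and `sensor`
#'   (lists of matrices), `times` (hours) and `config`.
#' @export
render_movie <- function(cohort, frames = NULL, noise = TRUE) {
  frames <- frames %||% seq_along(cohort$times)
  fr <- lapply(frames, function(f) render_frame(cohort, f, noise = noise))
  out <- list(h2b = lapply(fr, `[[`, "h2b"),
              sensor = lapply(fr, `[[`, "sensor"),
              frames = frames, times = cohort$times[frames],
              config = cohort$config)
  class(out) <- "image_stack"
  out
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("Synthetic image stack: %d frames, %d x %d px, 2 channels\n",
              length(x$frames), nrow(x$h2b[[1]]), ncol(x$h2b[[1]])))
  invisible(x)
}

#' Render the endpoint immunofluorescence image set
#'
#' Draws each surviving cell's expected IF intensity from the protein
#' profile set at its (fate, time-since-last-anaphase), applies lognormal
#' staining noise, renders nuclear (or, for cytoplasmic markers, ring)
#' signal plus a Hoechst nuclear channel, and rigidly translates the whole
#' IF set by the configured stage jitter. The applied shift is returned for
#' testing; prolonged-quiescent cells carry no anaphase and are evaluated on
#' the quiescent branch at the movie length.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param panel character vector of protein names (see [protein_profiles()]).
#' @param shift integer `c(dy, dx)` overriding the configured jitter.
#' @param noise add staining and pixel noise?
#' @return An object of class `if_set`: list with `images` (named list of
#'   matrices: `hoechst` plus one per panel protein), `shift`, and `truth`
#'   (per-cell data frame of fate, time since anaphase and true values).
#' @export
render_endpoint_if <- function(cohort, panel = c("CyclinA2", "p21", "EdU"),
                               shift = NULL, noise = TRUE) {
  config <- cohort$config
  profs <- protein_profiles(config$s_phase_window)
  unknown <- setdiff(panel, names(profs))
  if (length(unknown)) stop("unknown protein(s): ", paste(unknown, collapse = ", "))
  nf <- config$n_frames
  alive <- which(cohort$cells$end_frame == nf)
  cells <- cohort$cells[alive, ]
  tau <- config$duration - cells$division_time   # NA for nondividers

  with_seed(derived_seed(config$seed, 900001), {
  if (is.null(shift)) {
    shift <- if (identical(config$jitter_shift, "random")) {
      sample(seq(-config$jitter_radius, config$jitter_radius), 2, replace = TRUE)
    } else as.integer(config$jitter_shift)
  }
  shift <- as.integer(shift)

  # effective (fate, tau) seen by the profiles: emerging cells recapitulate
  # the cycling program measured from their R-point
  eff_fate <- cells$fate
  eff_tau <- tau
  em <- cells$fate %in% c("CDK2emerge", "nondividing_emerge")
  eff_tau[em] <- pmax(0, config$duration - cells$rpoint_time[em])
  pq <- cells$fate == "prolonged_quiescent"
  eff_tau[pq] <- config$duration

  truth <- data.frame(id = cells$id, fate = cells$fate,
                      time_since_anaphase = tau, stringsAsFactors = FALSE)
  sdlog <- if (noise) config$if_noise_sdlog else 0
  values <- list()
  for (p in panel) {
    v <- vapply(seq_len(nrow(cells)), function(k) {
      profs[[p]](eff_fate[k], eff_tau[k])
    }, numeric(1))
    if (sdlog > 0) v <- v * exp(stats::rnorm(length(v), 0, sdlog))
    truth[[p]] <- v
    values[[p]] <- v
  }

  ar <- frame_areas(cohort, nf, alive)
  nuc_vals <- matrix(0, nrow(cells), 1 + length(panel),
                     dimnames = list(NULL, c("hoechst", panel)))
  cyto_vals <- nuc_vals
  nuc_vals[, "hoechst"] <- cells$h2b_mass / pmax(1L, ar$a_n)
  for (p in panel) {
    if (p %in% cytoplasmic_markers()) {
      # cytoplasmic marker: ring signal plus a dim nuclear floor
      nuc_vals[, p] <- 0.15 * values[[p]]
      cyto_vals[, p] <- values[[p]]
    } else {
      nuc_vals[, p] <- values[[p]]
    }
  }
  imgs <- render_values(cohort, nf, nuc_vals, cyto_vals, alive)
  imgs <- lapply(imgs, function(m) {
    m <- shift_matrix(m, shift[1], shift[2], fill = config$background_level)
    if (noise && config$noise_sd > 0) {
      m <- m + stats::rnorm(length(m), 0, config$noise_sd)
      m[m < 0] <- 0
    }
    m
  })
  out <- list(images = imgs, shift = shift, truth = truth, config = config)
  class(out) <- "if_set"
  out
  })
}

#' Simulate an asynchronous snapshot IF population
#'
#' Generates a per-cell marker table emulating a fixed, asynchronously
#' cycling population stained for DNA content (Hoechst), EdU, phospho-Rb,
#' phospho-histone H3 and one protein of interest, together with
#' ground-truth phase labels. DNA content spans 2N-4N, EdU is trimodal
#' (negative / intermediate in early and late S / high in mid-S), phospho-Rb
#' is bimodal with the hypo-phosphorylated mode confined to G0, and pHH3 is
#' positive only in mitosis. Measurement noise is lognormal.
#'
#' @param n number of cells.
#' @param occupancy named phase fractions over
#'   `G0, G1, earlyS, S, lateS, G2, M` (must sum to 1).
#' @param noise_sdlog lognormal measurement noise (0 = noiseless).
#' @param poi_means named per-phase mean of the protein of interest.
#' @param dna_2n intensity of the 2N DNA peak, arbitrary units.
#' @param seed integer seed.
#' @return data frame with columns `dna`, `edu`, `prb`, `phh3`, `poi` and
#'   `true_phase`.
#' @export
snapshot_population <- function(n = 5000,
                                occupancy = c(G0 = 0.15, G1 = 0.25,
                                              earlyS = 0.06, S = 0.20,
                                              lateS = 0.06, G2 = 0.20,
                                              M = 0.08),
                                noise_sdlog = 0.15,
                                poi_means = c(G0 = 600, G1 = 80, earlyS = 80,
                                              S = 70, lateS = 70, G2 = 80,
                                              M = 120),
                                dna_2n = 5000,
                                seed = 1) {
  phases <- c("G0", "G1", "earlyS", "S", "lateS", "G2", "M")
  if (!all(phases %in% names(occupancy))) stop("occupancy must name all 7 phases")
  occupancy <- occupancy[phases]
  if (any(occupancy < 0) || abs(sum(occupancy) - 1) > 1e-9) {
    stop("occupancy fractions must be nonnegative and sum to 1")
  }
  set.seed(seed)
  ph <- sample(phases, n, replace = TRUE, prob = occupancy)
  dna_mult <- c(G0 = 2, G1 = 2, earlyS = 2.1, S = NA, lateS = 3.8,
                G2 = 4, M = 4)
  dna <- dna_mult[ph] * dna_2n / 2
  inS <- ph == "S"
  dna[inS] <- stats::runif(sum(inS), 2.3, 3.5) * dna_2n / 2
  edu <- c(G0 = 30, G1 = 30, earlyS = 300, S = 3000, lateS = 300,
           G2 = 30, M = 30)[ph]
  prb <- ifelse(ph == "G0", 100, 1000)
  phh3 <- ifelse(ph == "M", 2000, 50)
  poi <- poi_means[ph]
  jitter <- function(x) {
    if (noise_sdlog <= 0) return(as.numeric(x))
    x * exp(stats::rnorm(n, 0, noise_sdlog))
  }
  data.frame(dna = jitter(dna), edu = jitter(edu), prb = jitter(prb),
             phh3 = jitter(phh3), poi = jitter(poi),
             true_phase = ph, stringsAsFactors = FALSE)
}
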