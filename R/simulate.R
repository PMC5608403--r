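#' Deterministic CDK2 activity law for one trace model
#'
#' Evaluates the noise-free activity series of a trace model on a grid of
#' times. Times are measured from the model's reference point: anaphase for
#' post-mitotic fates, movie start for nondividing fates. The functional
#' forms are piecewise linear: CDK2-increasing cells are born above the 0.5
#' threshold and rise linearly; CDK2-low cells sit flat below 0.5;
#' CDK2-emerging cells dwell at a low level for at least `emerge_delay`
#' hours (3 h minimum) and then rise linearly; prolonged-quiescent cells
#' stay below 0.6 throughout.
#'
#' @param model a list with at least `fate`, and the fields that fate uses:
#'   `birth_activity`, `rise_rate` (per hour), `low_level`, `emerge_delay`
#'   (hours), and optionally `cap` (default 2.4).
#' @param times increasing numeric vector of hours since the reference point.
#' @return numeric activity series, same length as `times`.
#' @export
sample_trace <- function(model, times) {
  if (is.unsorted(times)) stop("times must be increasing")
  cap <- model$cap %||% 2.4
  fate <- model$fate
  if (fate == "CDK2inc") {
    if (model$birth_activity < 0.5) {
      stop("CDK2inc birth_activity must be >= 0.5")
    }
    return(pmin(cap, model$birth_activity + model$rise_rate * times))
  }
  if (fate == "CDK2low" || fate == "prolonged_quiescent") {
    lim <- if (fate == "CDK2low") 0.5 else 0.6
    if (model$low_level >= lim) {
      stop(sprintf("%s low_level must be < %.1f", fate, lim))
    }
    return(rep(model$low_level, length(times)))
  }
  if (fate %in% c("CDK2emerge", "nondividing_emerge")) {
    if (fate == "CDK2emerge" && model$emerge_delay < 3) {
      stop("CDK2emerge emerge_delay must be >= 3 hours")
    }
    if (model$low_level >= 0.5) stop("emerge low_level must be < 0.5")
    return(pmin(cap, model$low_level +
                  model$rise_rate * pmax(0, times - model$emerge_delay)))
  }
  stop("unknown fate: ", fate)
}

# Draw the per-cell trace model for a fate. `duration` bounds event times so
# that each fate's defining behavior is observable within the movie.
draw_trace_model <- function(fate, duration) {
  m <- list(fate = fate)
  if (fate == "CDK2inc") {
    m$next_division_time <- stats::runif(1, 0.5, duration - 1.5)
    m$birth_activity <- stats::runif(1, 0.60, 0.80)
    m$rise_rate <- stats::runif(1, 0.05, 0.09)
  } else if (fate == "CDK2low") {
    m$next_division_time <- stats::runif(1, 0.5, duration - 1.5)
    m$low_level <- stats::runif(1, 0.20, 0.35)
  } else if (fate == "CDK2emerge") {
    m$next_division_time <- stats::runif(1, 0.5, duration - 10)
    m$low_level <- stats::runif(1, 0.20, 0.32)
    m$emerge_delay <- stats::runif(1, 3.5,
                                   min(10, duration - m$next_division_time - 4))
    m$rise_rate <- stats::runif(1, 0.20, 0.35)
  } else if (fate == "prolonged_quiescent") {
    m$low_level <- stats::runif(1, 0.20, 0.40)
  } else if (fate == "nondividing_emerge") {
    m$low_level <- stats::runif(1, 0.20, 0.35)
    m$emerge_delay <- stats::runif(1, 2, duration - 6)
    m$rise_rate <- stats::runif(1, 0.20, 0.35)
  } else {
    stop("unknown fate: ", fate)
  }
  if (!is.null(m$next_division_time)) {
    # pre-anaphase (mother) ramp: activity peaks just before division
    m$mother_peak <- stats::runif(1, 1.6, 2.2)
    m$mother_rate <- stats::runif(1, 0.06, 0.09)
    m$split_fraction <- min(0.52, max(0.48, stats::rnorm(1, 0.5, 0.008)))
    m$division_axis <- stats::runif(1, 0, 2 * pi)
  }
  m
}

# Seed initial positions with a minimum pairwise separation (dart throwing).
seed_positions <- function(n, shape, margin, dmin) {
  pos <- matrix(NA_real_, n, 2)
  k <- 0L; tries <- 0L
  while (k < n) {
    p <- c(stats::runif(1, margin, shape[1] - margin),
           stats::runif(1, margin, shape[2] - margin))
    ok <- k == 0L ||
      min((pos[seq_len(k), 1] - p[1])^2 + (pos[seq_len(k), 2] - p[2])^2) >= dmin^2
    tries <- tries + 1L
    if (ok) { k <- k + 1L; pos[k, ] <- p; tries <- 0L }
    if (tries > 2000L) {
      dmin <- dmin * 0.95; tries <- 0L
      warning("field crowded; relaxing minimum nucleus separation")
      if (dmin < 2) stop("field too small for n_cells")
    }
  }
  pos
}

#' Simulate a ground-truth cohort
#'
#' Draws per-cell fates from the configured composition, samples each cell's
#' trace model, and lays out full ground truth: activity traces on the frame
#' grid (with biological fluctuation), division times and geometry, lineage,
#' positions over time, and restriction-point times. Dividing cells have one
#' anaphase during the movie at which the mother is replaced by two
#' daughters whose H2B masses are each 45-55% of the mother's.
#'
#' @param config a [sim_config()] object.
#' @return An object of class `cohort`: a list with `cells` (one row per
#'   physical cell, mothers and daughters), `activity` (cells x frames true
#'   activity, `NA` when a cell does not exist), `pos_row`/`pos_col`
#'   matrices, `times` (hours) and the `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  times <- frame_times(config)
  nf <- config$n_frames
  n0 <- config$n_cells
  fates <- sample(names(config$composition), n0, replace = TRUE,
                  prob = config$composition)
  models <- lapply(fates, draw_trace_model, duration = config$duration)

  r_px <- config$r_px
  margin <- 3 * r_px + config$cyto_width
  dmin <- 4.8 * r_px * config$crowding
  pos0 <- seed_positions(n0, config$field_shape, margin, dmin)

  dividing <- !vapply(models, function(m) is.null(m$next_division_time),
                      logical(1))
  n_total <- n0 + 2L * sum(dividing)
  cells <- data.frame(
    id = seq_len(n_total), root_id = NA_integer_, mother_id = NA_integer_,
    fate = NA_character_, is_root = FALSE,
    birth_frame = NA_integer_, end_frame = NA_integer_,
    division_time = NA_real_, anaphase_frame = NA_integer_,
    rpoint_time = NA_real_, h2b_mass = NA_real_, radius = NA_real_,
    stringsAsFactors = FALSE)
  activity <- matrix(NA_real_, n_total, nf)
  pos_row <- matrix(NA_real_, n_total, nf)
  pos_col <- matrix(NA_real_, n_total, nf)

  nxt <- n0
  for (i in seq_len(n0)) {
    m <- models[[i]]
    cells$root_id[i] <- i; cells$is_root[i] <- TRUE
    cells$fate[i] <- fates[i]
    cells$birth_frame[i] <- 1L
    mass <- stats::rnorm(1, config$h2b_mass_mean,
                         config$h2b_mass_cv * config$h2b_mass_mean)
    mass <- max(mass, 0.4 * config$h2b_mass_mean)
    cells$h2b_mass[i] <- mass
    cells$radius[i] <- r_px
    if (!dividing[i]) {
      cells$end_frame[i] <- nf
      base <- sample_trace(m, times)
      activity[i, ] <- pmax(0.05, base +
                              stats::rnorm(nf, 0, config$trace_noise_sd))
      if (fates[i] == "nondividing_emerge") cells$rpoint_time[i] <- m$emerge_delay
      next
    }
    td <- m$next_division_time
    af <- which(times >= td)[1]           # first frame with two daughters
    cells$division_time[i] <- td
    cells$end_frame[i] <- af - 1L
    mother_t <- times[seq_len(af - 1L)]
    base <- pmax(0.5, m$mother_peak - m$mother_rate * (td - mother_t))
    activity[i, seq_len(af - 1L)] <-
      pmax(0.05, base + stats::rnorm(af - 1L, 0, config$trace_noise_sd))
    fr <- c(m$split_fraction, 1 - m$split_fraction)
    for (d in 1:2) {
      nxt <- nxt + 1L
      cells$id[nxt] <- nxt
      cells$root_id[nxt] <- i; cells$mother_id[nxt] <- i
      cells$fate[nxt] <- fates[i]
      cells$birth_frame[nxt] <- af; cells$end_frame[nxt] <- nf
      cells$anaphase_frame[nxt] <- af
      cells$division_time[nxt] <- td
      cells$h2b_mass[nxt] <- cells$h2b_mass[i] * fr[d]
      cells$radius[nxt] <- r_px / sqrt(2)
      tau <- times[af:nf] - td
      base_d <- sample_trace(m, tau)
      activity[nxt, af:nf] <-
        pmax(0.05, base_d + stats::rnorm(nf - af + 1L, 0,
                                         config$trace_noise_sd))
      if (fates[i] == "CDK2emerge") {
        cells$rpoint_time[nxt] <- td + m$emerge_delay
      } else if (fates[i] == "CDK2inc") {
        cells$rpoint_time[nxt] <- td
      }
    }
  }

  # --- positions: random walk with hard-core exclusion ---------------------
  # nuclei are impenetrable: after each diffusion step, overlapping pairs
  # are pushed apart so centers stay >= r_i + r_j + 1 px apart (nuclei may
  # touch but not interpenetrate)
  root_axis <- vapply(models, function(m) m$division_axis %||% NA_real_,
                      numeric(1))
  resolve_overlaps <- function(idx, pr, pc) {
    # clamp to the field margin first; exclusion runs last so that cells
    # pushed off a crowded margin stay separated (they may intrude a few
    # pixels into the margin, which the renderer tolerates)
    pr <- pmin(pmax(pr, margin), config$field_shape[1] - margin)
    pc <- pmin(pmax(pc, margin), config$field_shape[2] - margin)
    resolve_overlaps_cpp(pr, pc, cells$radius[idx], config$contact_gap, 10L)
  }
  pos_row[seq_len(n0), 1L] <- pos0[, 1]
  pos_col[seq_len(n0), 1L] <- pos0[, 2]
  for (f in 2:nf) {
    cont <- which(cells$birth_frame < f & cells$end_frame >= f)
    if (length(cont)) {
      pos_row[cont, f] <- pos_row[cont, f - 1L] +
        stats::rnorm(length(cont), 0, config$motion_sd)
      pos_col[cont, f] <- pos_col[cont, f - 1L] +
        stats::rnorm(length(cont), 0, config$motion_sd)
    }
    born <- which(cells$birth_frame == f)
    for (b in born) {
      mo <- cells$mother_id[b]
      ax <- root_axis[mo]
      sgn <- if (match(b, born[cells$mother_id[born] == mo]) == 1L) 1 else -1
      off <- cells$radius[mo] * c(cos(ax), sin(ax)) * sgn
      pos_row[b, f] <- pos_row[mo, f - 1L] + off[1]
      pos_col[b, f] <- pos_col[mo, f - 1L] + off[2]
    }
    alive <- which(cells$birth_frame <= f & cells$end_frame >= f)
    rs <- resolve_overlaps(alive, pos_row[alive, f], pos_col[alive, f])
    pos_row[alive, f] <- rs$pr
    pos_col[alive, f] <- rs$pc
  }

  out <- list(cells = cells, activity = activity,
              pos_row = pos_row, pos_col = pos_col,
              times = times, models = models, config = config)
  class(out) <- "cohort"
  out
}

#' @export
print.cohort <- function(x, ...) {
  roots <- x$cells[x$cells$is_root, ]
  cat(sprintf("Synthetic cohort: %d starting cells (%d physical cells, %d frames)\n",
              nrow(roots), nrow(x$cells), length(x$times)))
  print(table(roots$fate))
  invisible(x)
}

#' @export
summary.cohort <- function(object, ...) {
  roots <- object$cells[object$cells$is_root, ]
  divided <- !is.na(roots$division_time)
  cat(sprintf("%d cells; %.1f%% divided at least once\n",
              nrow(roots), 100 * mean(divided)))
  print(round(100 * prop.table(table(roots$fate)), 2))
  invisible(object)
}
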