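# Protein dynamics maps: endpoint IF values placed on the computational
# time axis (time since anaphase or since R-point), per-fate moving-average
# curves with SD error bars, shared min-max normalization of the
# proliferating/quiescent pair, and the Group 1 / Group 2 partition of
# protein behaviors in quiescent cells.

#' Reconstruct protein dynamics versus time since anchor
#'
#' One point per cell: x is the fixation time minus the anchor time (time
#' since last anaphase, or since R-point), y the matched endpoint IF value.
#' Prolonged-quiescent cells carry no anaphase and are plotted at the movie
#' length (the 24-hour mark by default).
#'
#' @param ensemble an [align_ensemble()] result.
#' @param if_values data frame of matched IF values with a `track` column
#'   (see [match_if_to_traces()]; `label` is matched against the terminal
#'   track's final-frame label by the pipeline) and one column per protein.
#' @param protein column of `if_values` to map.
#' @param fate fate class to select (`NULL` = all).
#' @param movie_length hours; x position assigned to prolonged-quiescent
#'   cells.
#' @return data frame `time`, `value`, `fate`, `track`.
#' @export
reconstruct_dynamics <- function(ensemble, if_values, protein,
                                 fate = NULL, movie_length = 24) {
  a <- ensemble$anchors
  m <- merge(a, if_values, by = "track")
  if (!is.null(fate)) m <- m[m$fate %in% fate, ]
  x <- m$if_time
  x[m$fate == "prolonged_quiescent"] <- movie_length
  out <- data.frame(time = x, value = m[[protein]], fate = m$fate,
                    track = m$track, stringsAsFactors = FALSE)
  out[is.finite(out$value) & is.finite(out$time), , drop = FALSE]
}

#' Moving average of a reconstructed scatter
#'
#' Sliding-window mean and standard deviation of `value` versus `time`:
#' windows of width `window` hours advance by `step`; bins holding fewer
#' than `min_bin_count` points are suppressed.
#'
#' @param scatter data frame with `time` and `value` (see
#'   [reconstruct_dynamics()]).
#' @param window window width in hours.
#' @param step hours between successive bin centers.
#' @param min_bin_count minimum points per reported bin.
#' @return An object of class `dynamics_curve`: data frame `time` (bin
#'   center), `mean`, `sd`, `n`.
#' @export
moving_average <- function(scatter, window = 2, step = 0.5,
                           min_bin_count = 10) {
  if (nrow(scatter) == 0L) {
    out <- data.frame(time = numeric(0), mean = numeric(0),
                      sd = numeric(0), n = integer(0))
    class(out) <- c("dynamics_curve", "data.frame")
    return(out)
  }
  centers <- seq(min(scatter$time), max(scatter$time), by = step)
  rows <- lapply(centers, function(ct) {
    sel <- abs(scatter$time - ct) <= window / 2
    n <- sum(sel)
    if (n < min_bin_count) return(NULL)
    data.frame(time = ct, mean = mean(scatter$value[sel]),
               sd = stats::sd(scatter$value[sel]), n = n)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(time = numeric(0), mean = numeric(0),
                      sd = numeric(0), n = integer(0))
  }
  class(out) <- c("dynamics_curve", "data.frame")
  out
}

#' @export
plot.dynamics_curve <- function(x, ..., add = FALSE, col = "steelblue") {
  if (nrow(x) == 0L) stop("empty curve")
  if (!add) {
    plot(x$time, x$mean, type = "n",
         ylim = range(c(x$mean - x$sd, x$mean + x$sd), na.rm = TRUE),
         xlab = "time since anchor (h)", ylab = "IF signal (AU)", ...)
  }
  graphics::arrows(x$time, x$mean - x$sd, x$time, x$mean + x$sd,
                   angle = 90, code = 3, length = 0.02, col = col)
  graphics::lines(x$time, x$mean, col = col, lwd = 2)
  invisible(x)
}

#' Shared min-max normalization of a proliferating/quiescent curve pair
#'
#' Affine rescaling using one shared minimum and maximum across both
#' curves: the smallest signal across the CDK2-increasing and CDK2-low
#' curves maps to 0 and the largest to 1, preserving the relative levels of
#' the two classes.
#'
#' @param curve_inc,curve_low `dynamics_curve` objects (or data frames with
#'   `mean`).
#' @return list of class `normalized_pair` with rescaled `inc` and `low`
#'   curves (sd rescaled by the same factor) and the shared `range`.
#' @export
normalize_pair <- function(curve_inc, curve_low) {
  if (nrow(curve_inc) == 0L || nrow(curve_low) == 0L) {
    stop("both curves must be nonempty")
  }
  lo <- min(curve_inc$mean, curve_low$mean)
  hi <- max(curve_inc$mean, curve_low$mean)
  if (hi <= lo) stop("flat curve pair: max equals min, cannot normalize")
  rs <- function(cv) {
    cv$mean <- (cv$mean - lo) / (hi - lo)
    if (!is.null(cv$sd)) cv$sd <- cv$sd / (hi - lo)
    cv
  }
  structure(list(inc = rs(curve_inc), low = rs(curve_low),
                 range = c(min = lo, max = hi)),
            class = "normalized_pair")
}

#' Group 1 / Group 2 assignment of a quiescent-cell curve
#'
#' Group 1 proteins are "off" in quiescent cells: the normalized CDK2-low
#' curve is flat (total range below `flat_tolerance`) and stays below a
#' low-level ceiling. Everything else — signals that sit high or change
#' dynamically during quiescence — is Group 2.
#'
#' @param curve_low normalized CDK2-low curve (from [normalize_pair()]).
#' @param flat_tolerance maximum normalized range still considered flat.
#' @param level_ceiling maximum normalized level for an "off" signal.
#' @return `"Group1"`, `"Group2"`, or `"unassigned"` for curves with fewer
#'   than 3 bins.
#' @export
assign_group <- function(curve_low, flat_tolerance = 0.2,
                         level_ceiling = 0.25) {
  if (inherits(curve_low, "normalized_pair")) curve_low <- curve_low$low
  if (nrow(curve_low) < 3L) return("unassigned")
  rng <- max(curve_low$mean) - min(curve_low$mean)
  if (rng < flat_tolerance && max(curve_low$mean) < level_ceiling) {
    "Group1"
  } else {
    "Group2"
  }
}

#' S-phase window from the EdU reconstruction
#'
#' The S-phase interval is where the CDK2-increasing EdU moving average
#' exceeds half of its maximum — the computational reading of the EdU
#' "rainbow" that annotates G1/S/G2 on the dynamics maps.
#'
#' @param edu_curve `dynamics_curve` of EdU for CDK2-increasing cells.
#' @return `c(start, end)` hours since anaphase.
#' @export
s_phase_window_from_edu <- function(edu_curve) {
  if (nrow(edu_curve) < 3L) stop("EdU curve too short")
  half <- min(edu_curve$mean) + 0.5 * (max(edu_curve$mean) - min(edu_curve$mean))
  hi <- edu_curve$time[edu_curve$mean > half]
  c(min(hi), max(hi))
}
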