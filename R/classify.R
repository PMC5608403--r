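#' Trace classifier parameters
#'
#' Thresholds of the fate rules. Post-mitotic classes use the 0.5 activity
#' threshold evaluated at every post-anaphase frame; prolonged quiescence
#' uses 0.6 over the whole movie; the two constants are kept separate on
#' purpose.
#'
#' @param inc_threshold activity threshold for the post-mitotic rules.
#' @param emerge_min_low minimum hours a CDK2-emerging trace must stay below
#'   `inc_threshold` after anaphase before rising.
#' @param prolonged_threshold activity ceiling for prolonged quiescence
#'   (nondividing cells).
#' @param movie_length hours of imaging.
#' @param rise_confirm consecutive frames at/above threshold that confirm a
#'   rise.
#' @param grace_period hours after anaphase ignored by the post-mitotic
#'   predicates (0 = strict all-frames rule; 2 reproduces the variant that
#'   scores traces from 2 h after mitosis).
#' @return list of class `classifier_params`.
#' @export
classifier_params <- function(inc_threshold = 0.5, emerge_min_low = 3,
                              prolonged_threshold = 0.6, movie_length = 24,
                              rise_confirm = 3, grace_period = 0) {
  if (inc_threshold <= 0 || prolonged_threshold <= 0) {
    stop("thresholds must be positive")
  }
  if (emerge_min_low < 0) stop("emerge_min_low must be >= 0")
  structure(list(inc_threshold = inc_threshold,
                 emerge_min_low = emerge_min_low,
                 prolonged_threshold = prolonged_threshold,
                 movie_length = movie_length, rise_confirm = rise_confirm,
                 grace_period = grace_period),
            class = "classifier_params")
}

# TRUE if `x` (logical) contains a run of at least k consecutive TRUE.
has_run <- function(x, k) {
  if (k <= 1L) return(any(x))
  r <- rle(x)
  any(r$values & r$lengths >= k)
}

#' Classify one CDK2 activity trace
#'
#' Dividing cells (trace carries an anaphase) are scored on their
#' post-anaphase frames: `CDK2inc` if the activity is at or above the
#' threshold at every frame, `CDK2low` if below at every frame,
#' `CDK2emerge` if below for at least `emerge_min_low` hours post-anaphase
#' followed by a confirmed rise, otherwise `unclassified`. Nondividing
#' cells are `prolonged_quiescent` if the activity stays below the
#' prolonged threshold for the whole movie, `nondividing_emerge` if a
#' confirmed rise above that threshold occurs, otherwise `unclassified`.
#' Missing frames are ignored (predicates run over observed frames only).
#'
#' @param activity numeric activity series (may contain `NA`).
#' @param times hours, same length; for a dividing cell, hours since the
#'   last anaphase (the series itself must start at the last anaphase).
#' @param divided logical: does this trace follow an anaphase?
#' @param params a [classifier_params()] object.
#' @return one of `"CDK2inc"`, `"CDK2low"`, `"CDK2emerge"`,
#'   `"prolonged_quiescent"`, `"nondividing_emerge"`, `"unclassified"`.
#' @export
classify_trace <- function(activity, times, divided,
                           params = classifier_params()) {
  keep <- !is.na(activity)
  activity <- activity[keep]; times <- times[keep]
  if (length(activity) < params$rise_confirm) return("unclassified")
  if (divided) {
    tau <- times - times[1]
    use <- tau >= params$grace_period
    a <- activity[use]; tau_u <- tau[use]
    if (length(a) < params$rise_confirm) return("unclassified")
    hi <- a >= params$inc_threshold
    if (all(hi)) return("CDK2inc")
    if (!any(hi)) return("CDK2low")
    early_low <- all(a[tau_u < params$emerge_min_low] < params$inc_threshold)
    confirmed <- has_run(hi, params$rise_confirm)
    if (early_low && confirmed) return("CDK2emerge")
    return("unclassified")
  }
  hi <- activity >= params$prolonged_threshold
  if (has_run(hi, params$rise_confirm)) return("nondividing_emerge")
  if (!any(hi)) return("prolonged_quiescent")
  "unclassified"
}

#' Classify every lineage of a tracked movie
#'
#' Follows each track present at the first frame through its divisions
#' (taking the first daughter at each anaphase) and classifies the lineage
#' on the trace after its last anaphase, or on the whole trace for
#' nondividing cells. This reproduces per-starting-cell population
#' fractions: each cell of the first frame contributes exactly one label.
#'
#' @param traces a `cell_traces` object from [assemble_traces()].
#' @param params a [classifier_params()] object.
#' @return data frame: track (root id), fate, divided, last_anaphase_frame.
#' @export
classify_lineages <- function(traces, params = classifier_params()) {
  roots <- traces$tracks$track[traces$tracks$start_frame == 1L &
                                 is.na(traces$tracks$mother_id)]
  res <- lapply(roots, function(r) {
    t_id <- r; last_ana <- NA_integer_
    repeat {
      daughters <- traces$tracks$track[!is.na(traces$tracks$mother_id) &
                                         traces$tracks$mother_id == t_id]
      if (length(daughters) == 0L) break
      t_id <- min(daughters)
      last_ana <- traces$tracks$anaphase_frame[traces$tracks$track == t_id]
    }
    s <- track_series(traces, t_id)
    fate <- classify_trace(s$activity, s$times, divided = !is.na(last_ana),
                           params = params)
    data.frame(track = r, terminal_track = t_id, fate = fate,
               divided = !is.na(last_ana), last_anaphase_frame = last_ana)
  })
  do.call(rbind, res)
}

#' Fate composition of a tracked movie
#'
#' @param traces a `cell_traces` object.
#' @param params a [classifier_params()] object.
#' @return named percentages over the fate labels (of all starting cells),
#'   plus `divided` (percent with at least one detected anaphase).
#' @export
fate_composition <- function(traces, params = classifier_params()) {
  cl <- classify_lineages(traces, params)
  lv <- c("CDK2inc", "CDK2low", "CDK2emerge", "prolonged_quiescent",
          "nondividing_emerge", "unclassified")
  tab <- table(factor(cl$fate, levels = lv))
  pct <- 100 * as.vector(tab) / nrow(cl)
  names(pct) <- lv
  c(pct, divided = 100 * mean(cl$divided))
}

#' Restriction-point detector parameters
#'
#' @param slope_windows window lengths (time points) over which activity
#'   slopes are fitted; the per-point slope is the maximum over windows.
#' @param w_time,w_activity,w_slope coefficients of the linear score
#'   favoring long time since mitosis (`w_time >= 0`), low activity
#'   (`w_activity` enters negatively) and high slope (`w_slope >= 0`).
#'   Defaults were tuned once on simulated emerging traces (independent of
#'   the test seeds) to well under an hour of median detection error.
#' @param noise_floor minimum slope (activity/hour) for a rise to count.
#' @return list of class `rpoint_params`.
#' @export
rpoint_params <- function(slope_windows = 6:10, w_time = 0.02,
                          w_activity = 1.0, w_slope = 1,
                          noise_floor = 0.05) {
  if (any(slope_windows < 2)) stop("slope windows must have length >= 2")
  if (w_time < 0 || w_slope < 0) stop("w_time and w_slope must be >= 0")
  structure(list(slope_windows = as.integer(slope_windows), w_time = w_time,
                 w_activity = abs(w_activity), w_slope = w_slope,
                 noise_floor = noise_floor),
            class = "rpoint_params")
}

# OLS slope of y over x (closed form).
ols_slope <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sum((x - mx)^2)
}

#' Detect the restriction point of a trace
#'
#' The R-point is the time CDK2 activity first begins to rise: activity
#' slopes are computed over forward-looking windows of 6-10 time points,
#' the per-point slope is the maximum across windows, and the linear score
#' `w_time * t - w_activity * activity + w_slope * slope` is maximized over
#' the trace. Returns `NA` for flat traces (no slope above the noise
#' floor).
#'
#' @param activity numeric activity series.
#' @param times hours (since mitosis for post-anaphase traces).
#' @param params an [rpoint_params()] object.
#' @return time (hours) of the detected R-point, or `NA`.
#' @export
detect_rpoint <- function(activity, times, params = rpoint_params()) {
  keep <- !is.na(activity)
  activity <- activity[keep]; times <- times[keep]
  n <- length(activity)
  if (n < min(params$slope_windows)) return(NA_real_)
  slope <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    s <- -Inf
    for (w in params$slope_windows) {
      if (i + w - 1L > n) next
      idx <- i:(i + w - 1L)
      s <- max(s, ols_slope(times[idx], activity[idx]))
    }
    if (is.finite(s)) slope[i] <- s
  }
  if (all(is.na(slope)) || max(slope, na.rm = TRUE) <= params$noise_floor) {
    return(NA_real_)
  }
  score <- params$w_time * times - params$w_activity * activity +
    params$w_slope * slope
  times[which.max(score)]
}

#' Align an ensemble of traces to a common anchor
#'
#' Shifts each trace's time axis so that its anchor (last anaphase, or
#' detected R-point) sits at 0, reconstructing computational
#' synchronization of an asynchronous population. Endpoint IF values, when
#' attached, inherit `fixation time - anchor time` as their x-coordinate.
#'
#' @param traces a `cell_traces` object.
#' @param anchor `"anaphase"` or `"rpoint"`.
#' @param fates optional result of [classify_lineages()] (computed if
#'   missing); classification supplies the anchor for each lineage.
#' @param classifier,rpoint parameter objects.
#' @return An object of class `aligned_ensemble`: `series` (long data frame
#'   track/time/activity), `anchors` (track, fate, anchor_time, fixation
#'   offset `if_time`), and `anchor` type. Traces without the anchor are
#'   dropped with a warning.
#' @export
align_ensemble <- function(traces, anchor = c("anaphase", "rpoint"),
                           fates = NULL,
                           classifier = classifier_params(),
                           rpoint = rpoint_params()) {
  anchor <- match.arg(anchor)
  if (is.null(fates)) fates <- classify_lineages(traces, classifier)
  fix_time <- traces$times[length(traces$times)]
  rows <- list(); anch <- list()
  dropped <- 0L
  for (k in seq_len(nrow(fates))) {
    t_id <- fates$terminal_track[k]
    s <- track_series(traces, t_id)
    a_time <- if (anchor == "anaphase") {
      if (is.na(fates$last_anaphase_frame[k])) NA_real_
      else traces$times[fates$last_anaphase_frame[k]]
    } else {
      rp <- detect_rpoint(s$activity, s$times - s$times[1], rpoint)
      if (is.na(rp)) NA_real_ else rp + s$times[1]
    }
    if (is.na(a_time)) {
      if (fates$fate[k] == "prolonged_quiescent") {
        # kept without an anchor: dynamics maps place these cells at the
        # movie-length mark
        anch[[length(anch) + 1L]] <-
          data.frame(track = fates$track[k], fate = fates$fate[k],
                     anchor_time = NA_real_, if_time = NA_real_,
                     stringsAsFactors = FALSE)
      } else {
        dropped <- dropped + 1L
      }
      next
    }
    # include the full lineage history (root through terminal track)
    chain <- t_id
    repeat {
      m <- traces$tracks$mother_id[traces$tracks$track == chain[1]]
      if (is.na(m)) break
      chain <- c(m, chain)
    }
    o <- traces$obs[traces$obs$track %in% chain, ]
    rows[[length(rows) + 1L]] <-
      data.frame(track = fates$track[k], time = traces$times[o$frame] - a_time,
                 activity = o$cdk2_activity, fate = fates$fate[k],
                 stringsAsFactors = FALSE)
    anch[[length(anch) + 1L]] <-
      data.frame(track = fates$track[k], fate = fates$fate[k],
                 anchor_time = a_time, if_time = fix_time - a_time,
                 stringsAsFactors = FALSE)
  }
  if (dropped > 0L) {
    warning(sprintf("%d trace(s) without %s anchor excluded", dropped, anchor))
  }
  out <- list(series = do.call(rbind, rows), anchors = do.call(rbind, anch),
              anchor = anchor)
  class(out) <- "aligned_ensemble"
  out
}
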