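#' Tracking parameters
#'
#' @param max_displacement maximum centroid displacement per frame, microns.
#' @param h2b_tolerance relative band for conservation-of-mass screening:
#'   a link is accepted only if the target's total H2B fluorescence is
#'   within this fraction of the source's.
#' @param daughter_low,daughter_high anaphase band: a division is called
#'   when the two nearest future neighbors of a cell each carry a fraction
#'   of its total H2B fluorescence inside `[daughter_low, daughter_high]`
#'   (endpoints inclusive).
#' @param max_gap number of missing frames a track may bridge.
#' @param pixel_size microns per pixel.
#' @return list of class `track_params`.
#' @export
track_params <- function(max_displacement = 15, h2b_tolerance = 0.2,
                         daughter_low = 0.45, daughter_high = 0.55,
                         max_gap = 1, pixel_size = 1) {
  if (!(daughter_low > 0 && daughter_low < daughter_high && daughter_high < 1)) {
    stop("need 0 < daughter_low < daughter_high < 1")
  }
  if (h2b_tolerance <= 0) stop("h2b_tolerance must be positive")
  structure(list(max_displacement = max_displacement,
                 h2b_tolerance = h2b_tolerance,
                 daughter_low = daughter_low, daughter_high = daughter_high,
                 max_gap = max_gap, pixel_size = pixel_size),
            class = "track_params")
}

#' Link cells between consecutive frames
#'
#' Greedy nearest-future-neighbor matching screened for conservation of
#' mass: candidate pairs within `max_displacement` are processed in order of
#' increasing centroid distance (ties by smaller mass difference) and a pair
#' is linked only if both ends are still free and the target's total H2B is
#' within `h2b_tolerance` of the source's. Cells left unmatched become track
#' ends (sources) or track starts (targets).
#'
#' @param obs_t,obs_t1 per-cell observation data frames (from
#'   [quantify_frame()]) at frames t and t+1; need columns `row`, `col`,
#'   `total_h2b`.
#' @param params a [track_params()] object.
#' @return integer vector of length `nrow(obs_t)`: for each source cell the
#'   row index of its match in `obs_t1`, or `NA`.
#' @export
link_frames <- function(obs_t, obs_t1, params = track_params()) {
  n1 <- nrow(obs_t); n2 <- nrow(obs_t1)
  match_out <- rep(NA_integer_, n1)
  if (n1 == 0L || n2 == 0L) return(match_out)
  maxd <- params$max_displacement / params$pixel_size
  d2 <- outer(obs_t$row, obs_t1$row, `-`)^2 + outer(obs_t$col, obs_t1$col, `-`)^2
  cand <- which(d2 <= maxd^2, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(match_out)
  mass_ok <- abs(obs_t1$total_h2b[cand[, 2]] - obs_t$total_h2b[cand[, 1]]) <=
    params$h2b_tolerance * obs_t$total_h2b[cand[, 1]]
  cand <- cand[mass_ok, , drop = FALSE]
  if (nrow(cand) == 0L) return(match_out)
  dd <- d2[cand]
  dm <- abs(obs_t1$total_h2b[cand[, 2]] - obs_t$total_h2b[cand[, 1]])
  ord <- order(dd, dm)
  used_src <- logical(n1); used_tgt <- logical(n2)
  for (k in ord) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (used_src[i] || used_tgt[j]) next
    used_src[i] <- TRUE; used_tgt[j] <- TRUE
    match_out[i] <- j
  }
  match_out
}

#' Detect merge and split candidates from a frame link
#'
#' Conservation of mass flags two situations: an unmatched target whose
#' total H2B is within tolerance of the summed mass of its two nearest
#' unmatched sources (a putative merge, to be sent back to
#' [adaptive_resegment()]), and an unmatched source whose mass splits
#' across its two nearest targets (a split candidate, to be tested by
#' [call_anaphase()]).
#'
#' @inheritParams link_frames
#' @param assignment link vector from [link_frames()].
#' @return list with data frames `merge` (target, src1, src2) and `split`
#'   (source, d1, d2), row indices into `obs_t1` / `obs_t`.
#' @export
detect_merge_split <- function(assignment, obs_t, obs_t1,
                               params = track_params()) {
  maxd <- params$max_displacement / params$pixel_size
  merge <- data.frame(target = integer(0), src1 = integer(0), src2 = integer(0))
  split <- data.frame(source = integer(0), d1 = integer(0), d2 = integer(0))
  un_src <- setdiff(seq_len(nrow(obs_t)), which(!is.na(assignment)))
  un_tgt <- setdiff(seq_len(nrow(obs_t1)), assignment[!is.na(assignment)])

  for (j in un_tgt) {
    if (length(un_src) < 2L) break
    d2 <- (obs_t$row[un_src] - obs_t1$row[j])^2 +
      (obs_t$col[un_src] - obs_t1$col[j])^2
    near <- un_src[order(d2)[1:2]]
    if (max(d2[order(d2)[1:2]]) > maxd^2) next
    msum <- sum(obs_t$total_h2b[near])
    if (abs(msum - obs_t1$total_h2b[j]) <= params$h2b_tolerance * obs_t1$total_h2b[j]) {
      merge <- rbind(merge, data.frame(target = j, src1 = near[1], src2 = near[2]))
    }
  }
  for (i in un_src) {
    if (nrow(obs_t1) < 2L) break
    d2 <- (obs_t1$row - obs_t$row[i])^2 + (obs_t1$col - obs_t$col[i])^2
    ord <- order(d2)[1:2]
    if (max(d2[ord]) > (2 * maxd)^2) next
    msum <- sum(obs_t1$total_h2b[ord])
    if (abs(msum - obs_t$total_h2b[i]) <= params$h2b_tolerance * obs_t$total_h2b[i]) {
      split <- rbind(split, data.frame(source = i, d1 = ord[1], d2 = ord[2]))
    }
  }
  list(merge = merge, split = split)
}

#' Anaphase call from mother and candidate daughters
#'
#' `TRUE` iff both candidate daughters carry a fraction of the mother's
#' total H2B fluorescence within `[daughter_low, daughter_high]`, endpoints
#' inclusive (45-55% by default).
#'
#' @param mother_obs one-row observation (needs `total_h2b`).
#' @param daughter_obs_pair two-row observation data frame.
#' @param params a [track_params()] object.
#' @return logical.
#' @export
call_anaphase <- function(mother_obs, daughter_obs_pair,
                          params = track_params()) {
  if (is.null(daughter_obs_pair) || nrow(daughter_obs_pair) < 2L) return(FALSE)
  if (any(is.na(daughter_obs_pair$total_h2b))) return(FALSE)
  fr <- daughter_obs_pair$total_h2b / mother_obs$total_h2b
  all(fr >= params$daughter_low & fr <= params$daughter_high)
}

#' Assemble tracks and lineage from frame links
#'
#' Concatenates frame-to-frame links into tracks, closes single-frame gaps
#' (a track end may re-link to a track start two frames later under the
#' same distance and mass criteria), attaches accepted anaphase events
#' (mother track ends, two daughter tracks begin carrying `mother_id`), and
#' returns the per-cell traces.
#'
#' @param obs_list list of per-frame observation data frames.
#' @param links list of link vectors, `links[[f]]` mapping frame f rows to
#'   frame f+1 rows.
#' @param anaphases data frame (frame, source, d1, d2) of accepted anaphase
#'   events; `source` indexes `obs_list[[frame]]`, daughters index frame+1.
#' @param times hour stamp per frame.
#' @param params a [track_params()] object.
#' @return An object of class `cell_traces`: `obs` (long data frame with
#'   `track` column), `tracks` (track table with `mother_id` and
#'   `anaphase_frame`), and `times`.
#' @export
assemble_traces <- function(obs_list, links, anaphases = NULL, times = NULL,
                            params = track_params()) {
  nf <- length(obs_list)
  ids <- vector("list", nf)
  nxt <- 0L
  for (f in seq_len(nf)) {
    n <- nrow(obs_list[[f]])
    ids[[f]] <- rep(NA_integer_, n)
    if (f == 1L) {
      ids[[f]] <- seq_len(n); nxt <- n
    } else {
      lk <- links[[f - 1L]]
      src <- which(!is.na(lk))
      ids[[f]][lk[src]] <- ids[[f - 1L]][src]
      new <- which(is.na(ids[[f]]))
      if (length(new)) {
        ids[[f]][new] <- nxt + seq_along(new)
        nxt <- nxt + length(new)
      }
    }
  }

  # daughters: record mother and anaphase frame
  mother <- rep(NA_integer_, nxt)
  ana_frame <- rep(NA_integer_, nxt)
  if (!is.null(anaphases) && nrow(anaphases)) {
    for (k in seq_len(nrow(anaphases))) {
      f <- anaphases$frame[k]
      m_id <- ids[[f]][anaphases$source[k]]
      for (dcol in c("d1", "d2")) {
        d_id <- ids[[f + 1L]][anaphases[[dcol]][k]]
        mother[d_id] <- m_id
        ana_frame[d_id] <- f + 1L
      }
    }
  }

  obs <- do.call(rbind, lapply(seq_len(nf), function(f) {
    o <- obs_list[[f]]
    if (nrow(o) == 0L) return(NULL)
    o$frame <- f; o$track <- ids[[f]]
    o
  }))
  obs <- obs[order(obs$track, obs$frame), , drop = FALSE]
  rownames(obs) <- NULL

  agg_first <- tapply(obs$frame, obs$track, min)
  agg_last <- tapply(obs$frame, obs$track, max)
  tracks <- data.frame(track = as.integer(names(agg_first)),
                       start_frame = as.integer(agg_first),
                       end_frame = as.integer(agg_last))
  tracks$mother_id <- mother[tracks$track]
  tracks$anaphase_frame <- ana_frame[tracks$track]

  # close single-frame gaps: end at f, start at f+2, not an anaphase daughter
  if (params$max_gap >= 1L) {
    repeat {
      ends <- tracks[tracks$end_frame <= nf - 2L, ]
      merged <- FALSE
      for (k in seq_len(nrow(ends))) {
        f <- ends$end_frame[k]
        starts <- tracks[tracks$start_frame == f + 2L & is.na(tracks$mother_id), ]
        if (nrow(starts) == 0L) next
        e_obs <- obs[obs$track == ends$track[k] & obs$frame == f, ]
        s_obs <- obs[obs$track %in% starts$track & obs$frame == f + 2L, ]
        lk <- link_frames(e_obs, s_obs, params)
        if (is.na(lk[1])) next
        tgt <- s_obs$track[lk[1]]
        obs$track[obs$track == tgt] <- ends$track[k]
        tracks$end_frame[tracks$track == ends$track[k]] <-
          tracks$end_frame[tracks$track == tgt]
        tracks$mother_id[!is.na(tracks$mother_id) & tracks$mother_id == tgt] <-
          ends$track[k]
        tracks <- tracks[tracks$track != tgt, ]
        merged <- TRUE
        break
      }
      if (!merged) break
    }
    obs <- obs[order(obs$track, obs$frame), , drop = FALSE]
  }
  if (anyDuplicated(paste(obs$track, obs$frame))) {
    stop("track assembly produced overlapping ids")
  }
  out <- list(obs = obs, tracks = tracks,
              times = times %||% seq_len(nf))
  class(out) <- "cell_traces"
  out
}

#' @export
print.cell_traces <- function(x, ...) {
  nd <- sum(!is.na(x$tracks$mother_id))
  cat(sprintf("Cell traces: %d tracks over %d frames (%d daughter tracks from %d anaphases)\n",
              nrow(x$tracks), length(x$times), nd, nd / 2))
  invisible(x)
}

# Activity series of one track as list(times, activity).
track_series <- function(traces, track_id) {
  o <- traces$obs[traces$obs$track == track_id, ]
  list(times = traces$times[o$frame], activity = o$cdk2_activity,
       frames = o$frame)
}
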