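#' Segmentation parameters
#'
#' @param log_sigma scale (pixels) of the Laplacian-of-Gaussian blob filter;
#'   defaults to `nucleus_radius_px / sqrt(2)`, the standard blob-scale
#'   match for disks of that radius.
#' @param response_threshold numeric threshold on the (sign-flipped) LoG
#'   filter response, or `"auto"` for Otsu's threshold on the response.
#' @param min_area,max_area accepted object area in pixels; default
#'   `[0.25, 4]` times the expected nucleus area.
#' @param concavity_angle_threshold minimum perimeter turning angle
#'   (degrees) for a boundary vertex to count as a concave deflection.
#' @param max_bridge_length maximum straight-cut length (pixels) joining two
#'   concave deflections.
#' @param nucleus_radius_px expected nucleus radius in pixels, used for the
#'   defaults above.
#' @return list of class `segment_params`.
#' @export
segment_params <- function(nucleus_radius_px = 5,
                           log_sigma = nucleus_radius_px / sqrt(2),
                           response_threshold = "auto",
                           min_area = round(0.25 * pi * nucleus_radius_px^2),
                           max_area = round(4 * pi * nucleus_radius_px^2),
                           concavity_angle_threshold = 15,
                           max_bridge_length = 4 * nucleus_radius_px) {
  if (log_sigma <= 0) stop("log_sigma must be positive")
  if (min_area >= max_area) stop("min_area must be < max_area")
  structure(list(log_sigma = log_sigma,
                 response_threshold = response_threshold,
                 min_area = min_area, max_area = max_area,
                 concavity_angle_threshold = concavity_angle_threshold,
                 max_bridge_length = max_bridge_length),
            class = "segment_params")
}

#' Segment nuclei in one frame
#'
#' Log-transforms the image (after adding a positive offset), convolves it
#' with a rotationally symmetric Laplacian-of-Gaussian filter, thresholds
#' the blob response (Otsu by default), labels contiguous pixels
#' (8-connected) and discards objects outside the accepted area range.
#'
#' @param image nonnegative intensity matrix.
#' @param params a [segment_params()] object.
#' @param offset positive offset added before the log transform.
#' @param refine trim the blob mask to the intensity edge (Otsu split of
#'   the log image); keeps nuclear masks from bleeding into the
#'   perinuclear cytoplasm.
#' @return An integer label matrix (0 = background) with attribute
#'   `"stats"`: a per-object data frame (label, area, centroid row/col).
#' @export
segment_nuclei <- function(image, params, offset = 1, refine = TRUE) {
  stopifnot(offset > 0)
  logim <- log(pmax(image, 0) + offset)
  resp <- log_response(logim, params$log_sigma)
  # large frames: estimate thresholds on a pixel subsample
  sub <- if (length(resp) > 3e5) {
    seq(1L, length(resp), by = max(1L, length(resp) %/% 2e5))
  } else seq_along(resp)
  thr <- params$response_threshold
  if (identical(thr, "auto")) {
    # robust noise floor: background dominates the response histogram, so
    # median + 5 MAD sits just above the noise while keeping blob interiors
    # (the LoG response crosses zero near the nucleus edge)
    v <- resp[sub]
    thr <- stats::median(v) + 5 * stats::mad(v) + 1e-9
    if (stats::sd(v) < 1e-8) thr <- Inf   # featureless frame: no objects
  }
  bw <- resp > thr
  # refine to the intensity edge: the LoG support bleeds 1-2 px past sharp
  # nuclear boundaries, so gate the blob mask at the Otsu intensity split
  # (background vs nuclear pixels) of the log image
  if (refine && stats::sd(logim[sub]) > 1e-8) {
    bw <- bw & (logim > otsu_threshold(logim[sub]))
  }
  lab <- label8(bw)
  st <- label_stats(lab)
  drop <- st$label[st$area < params$min_area | st$area > params$max_area]
  if (length(drop)) lab[lab %in% drop] <- 0L
  lab <- compact_labels(lab)
  attr(lab, "stats") <- label_stats(lab)
  lab
}

# Ordered boundary of a single object as 1-based (row, col) vertices.
object_contour <- function(mask) {
  oc <- EBImage::ocontour(EBImage::Image(mask))
  if (length(oc) == 0L) return(NULL)
  v <- oc[[which.max(vapply(oc, nrow, integer(1)))]] + 1  # 0-based -> 1-based
  colnames(v) <- c("row", "col")
  v
}

# Signed turning angles (degrees) at each vertex of a closed contour,
# computed on a circularly smoothed polygon. Positive = concave deflection
# (turn against the contour's overall orientation).
contour_concavity <- function(vertices, smooth_window = 5, lag = 3) {
  n <- nrow(vertices)
  if (n < 2 * lag + 1) return(rep(0, n))
  sm <- vertices
  half <- smooth_window %/% 2
  if (half > 0) {
    idx <- function(k) ((seq_len(n) - 1 + k) %% n) + 1
    acc <- matrix(0, n, 2)
    for (k in -half:half) acc <- acc + vertices[idx(k), ]
    sm <- acc / (2 * half + 1)
  }
  prv <- ((seq_len(n) - 1 - lag) %% n) + 1
  nxt <- ((seq_len(n) - 1 + lag) %% n) + 1
  v1 <- sm - sm[prv, , drop = FALSE]
  v2 <- sm[nxt, , drop = FALSE] - sm
  cross <- v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1]
  dot <- rowSums(v1 * v2)
  ang <- atan2(cross, dot) * 180 / pi
  # total turning is +/-360 deg depending on traversal orientation; convex
  # turns share its sign, so flip to make concave deflections positive
  -sign(sum(ang)) * ang
}

#' Split an object at concave perimeter deflections
#'
#' Detects concave inflections on the object's perimeter (turning angle on a
#' smoothed contour exceeding the concavity threshold), connects the best
#' admissible pair by a straight bridge (shortest bridge whose interior
#' stays inside the object, ties broken by deeper total concavity), removes
#' the bridge pixels, and recurses on the parts until no admissible pair
#' remains. Convex objects are returned unchanged.
#'
#' @param object_mask logical/0-1 matrix containing a single connected
#'   object.
#' @param params a [segment_params()] object.
#' @return Integer label matrix over the same shape: the input object
#'   partitioned into one or more regions (bridge cut pixels are 0).
#' @export
bridge_deflections <- function(object_mask, params) {
  mask <- object_mask > 0
  lab <- split_once(mask, params)
  compact_labels(lab)
}

split_once <- function(mask, params) {
  out <- matrix(0L, nrow(mask), ncol(mask))
  area <- sum(mask)
  if (area < 2 * params$min_area) { out[mask] <- 1L; return(out) }
  vert <- object_contour(mask)
  if (is.null(vert) || nrow(vert) < 8) { out[mask] <- 1L; return(out) }
  conc <- contour_concavity(vert)
  cand <- which(conc > params$concavity_angle_threshold)
  if (length(cand) < 2) { out[mask] <- 1L; return(out) }

  n <- nrow(vert)
  pairs <- t(utils::combn(cand, 2))
  d <- sqrt((vert[pairs[, 1], 1] - vert[pairs[, 2], 1])^2 +
              (vert[pairs[, 1], 2] - vert[pairs[, 2], 2])^2)
  sep <- pmin(abs(pairs[, 1] - pairs[, 2]),
              n - abs(pairs[, 1] - pairs[, 2]))
  ok <- d <= params$max_bridge_length & sep > 3 & d > 1
  if (!any(ok)) { out[mask] <- 1L; return(out) }
  pairs <- pairs[ok, , drop = FALSE]
  depth <- conc[pairs[, 1]] + conc[pairs[, 2]]
  ord <- order(d[ok], -depth)

  for (k in ord) {
    p1 <- vert[pairs[k, 1], ]; p2 <- vert[pairs[k, 2], ]
    # bridge interior must stay inside the object
    mid <- (p1 + p2) / 2
    ts <- seq(0.15, 0.85, by = 0.1)
    inside <- all(vapply(ts, function(t) {
      q <- round(p1 + t * (p2 - p1))
      mask[q[1], q[2]]
    }, logical(1)))
    if (!inside) next
    # width 0.75 is the narrowest straight cut that still disconnects an
    # 8-connected region (opposite-side diagonal neighbors are < 1.5 apart)
    cut <- segment_pixels(p1, p2, dim(mask), width = 0.75)
    trial <- mask
    trial[cut] <- FALSE
    parts <- label8(trial)
    np <- max(parts)
    if (np < 2) next
    sizes <- tabulate(parts[parts > 0], np)
    if (sum(sizes >= params$min_area) < 2) next
    # accept: recurse on each part
    for (p in seq_len(np)) {
      sub <- split_once(parts == p, params)
      sel <- sub > 0L
      out[sel] <- sub[sel] + max(out)
    }
    return(out)
  }
  out[mask] <- 1L
  out
}

#' Re-run deflection bridging on selected objects only
#'
#' Applies [bridge_deflections()] to the given suspect labels (typically
#' merge candidates flagged by the tracker) and leaves every other label
#' untouched.
#'
#' @param mask integer label matrix.
#' @param suspect_labels integer vector of labels to re-segment.
#' @param params a [segment_params()] object.
#' @return A relabeled integer matrix with attribute `"stats"`.
#' @export
adaptive_resegment <- function(mask, suspect_labels, params) {
  suspect_labels <- unique(as.integer(suspect_labels))
  if (length(suspect_labels) == 0L) {
    if (is.null(attr(mask, "stats"))) attr(mask, "stats") <- label_stats(mask)
    return(mask)
  }
  present <- unique(mask[mask > 0L])
  missing <- setdiff(suspect_labels, present)
  if (length(missing)) stop("unknown label id(s): ", paste(missing, collapse = ", "))
  out <- mask
  attr(out, "stats") <- NULL
  nxt <- max(mask)
  for (l in suspect_labels) {
    sel <- mask == l
    sub <- bridge_deflections(sel, params)
    k <- max(sub)
    out[sel] <- 0L
    if (k >= 1L) {
      first <- sub == 1L
      out[first] <- l                    # part 1 keeps the old label
      if (k > 1L) for (p in 2:k) {
        nxt <- nxt + 1L
        out[sub == p] <- nxt
      }
    }
  }
  out <- compact_labels(out)
  attr(out, "stats") <- label_stats(out)
  out
}

#' Segment a frame with full or adaptive bridging
#'
#' Convenience wrapper: [segment_nuclei()] followed by
#' [bridge_deflections()] on every object (`suspects = "all"`, the rule for
#' the first movie frame) or on a supplied suspect set (later frames).
#'
#' @inheritParams segment_nuclei
#' @param suspects `"all"`, `"none"`, or an integer label vector.
#' @return label matrix with `"stats"` attribute.
#' @export
segment_frame <- function(image, params, suspects = "all", offset = 1) {
  lab <- segment_nuclei(image, params, offset = offset)
  if (identical(suspects, "none")) return(lab)
  if (identical(suspects, "all")) suspects <- seq_len(max(lab))
  adaptive_resegment(lab, suspects, params)
}
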