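#' Quantification parameters
#'
#' @param local_bg_expand microns the nuclear mask is expanded by when
#'   estimating each cell's local background (median of non-masked pixels).
#' @param global_bg_dilate microns all nuclear masks are dilated by before
#'   computing the global background as the mode of the remaining pixels.
#' @param ring_inner_offset,ring_width perinuclear ring geometry in pixels:
#'   the ring is the mask dilated by `inner+width` minus the mask dilated by
#'   `inner`, excluding pixels of (or immediately adjacent to) other nuclei.
#' @param ring_percentile fraction of brightest ring pixels averaged for the
#'   cytoplasmic statistic (top 50% by default).
#' @param nuclear_floor minimum background-subtracted nuclear mean below
#'   which the activity ratio is marked missing rather than computed.
#' @param pixel_size microns per pixel, used to convert the micron
#'   distances.
#' @return list of class `quant_params`.
#' @export
quant_params <- function(local_bg_expand = 25, global_bg_dilate = 50,
                         ring_inner_offset = 1, ring_width = 4,
                         ring_percentile = 0.5, nuclear_floor = 20,
                         pixel_size = 1) {
  if (local_bg_expand <= 0 || global_bg_dilate <= 0 ||
      ring_inner_offset <= 0 || ring_width <= 0) {
    stop("all distances must be positive")
  }
  if (ring_percentile <= 0 || ring_percentile > 1) {
    stop("ring_percentile must be in (0, 1]")
  }
  structure(list(local_bg_expand = local_bg_expand,
                 global_bg_dilate = global_bg_dilate,
                 ring_inner_offset = ring_inner_offset,
                 ring_width = ring_width,
                 ring_percentile = ring_percentile,
                 nuclear_floor = nuclear_floor,
                 pixel_size = pixel_size),
            class = "quant_params")
}

# mean of the brightest `p` fraction of values ({1,2,3,4}, p=0.5 -> 3.5)
top_fraction_mean <- function(x, p) {
  n <- length(x)
  if (n == 0L) return(NA_real_)
  k <- max(1L, ceiling(p * n))
  mean(sort(x, decreasing = TRUE)[seq_len(k)])
}

#' Global background of a frame
#'
#' Dilates the nuclear mask by `global_bg_dilate` microns and returns the
#' mode intensity (integer-binned histogram) of all remaining pixels.
#'
#' @param image intensity matrix.
#' @param mask integer label (or logical) matrix of nuclei.
#' @param params a [quant_params()] object.
#' @return scalar mode intensity.
#' @export
global_background <- function(image, mask, params = quant_params(),
                              bg_dist = NULL) {
  r <- round(params$global_bg_dilate / params$pixel_size)
  bw <- mask > 0
  if (!any(bw)) return(stat_mode(image))
  d <- bg_dist %||% EBImage::distmap(matrix(as.numeric(!bw), nrow(bw)))
  keep <- d > r
  while (!any(keep) && r >= 2) {
    # small crowded fields: shrink the exclusion zone rather than fail
    r <- r %/% 2
    keep <- d > r
  }
  if (!any(keep)) stop("no non-masked pixels remain after dilation; field fully occupied")
  v <- image[keep]
  if (length(v) > 2e5) v <- v[seq(1L, length(v), by = ceiling(length(v) / 2e5))]
  stat_mode(v)
}

stat_mode <- function(x) {
  v <- round(as.numeric(x))
  tb <- tabulate(v - min(v) + 1L)
  (min(v) - 1L) + which.max(tb)
}

# Chebyshev distance from each pixel of a crop to a pixel set (brute force;
# used by the exact per-cell operations on small crops).
crop_cheb_dist <- function(rows, cols, px_rows, px_cols) {
  n1 <- length(rows); n2 <- length(cols); k <- length(px_rows)
  best <- rep(Inf, n1 * n2)
  grid_r <- rep(rows, times = n2)
  grid_c <- rep(cols, each = n1)
  for (j in seq_len(k)) {
    dj <- pmax(abs(grid_r - px_rows[j]), abs(grid_c - px_cols[j]))
    best <- pmin(best, dj)
  }
  matrix(best, n1, n2)
}

# Per-tile pooled background: mean intensity of pure-background pixels
# (bg_dist > guard) in each `tile` x `tile` block, smoothed over the 3x3
# tile neighborhood. Tiles whose neighborhood holds no pure pixel are NA.
tile_backgrounds <- function(images, mask, bg_dist, guard, tile = 32L) {
  nr <- nrow(mask); nc <- ncol(mask)
  ntr <- (nr + tile - 1L) %/% tile
  ntc <- (nc + tile - 1L) %/% tile
  pure <- which(bg_dist > guard)
  if (length(pure) > 4e5) pure <- pure[seq(1L, length(pure), by = 2L)]
  pr <- ((pure - 1L) %% nr) %/% tile
  pc <- ((pure - 1L) %/% nr) %/% tile
  tid <- 1L + pr + ntr * pc
  box3 <- function(m) {
    out <- matrix(0, nrow(m), ncol(m))
    for (dy in -1:1) for (dx in -1:1) {
      out <- out + shift_matrix(m, dy, dx, fill = 0)
    }
    out
  }
  cnt <- matrix(tabulate(tid, ntr * ntc), ntr, ntc)
  pooled_n <- box3(cnt)
  out <- list(tile = tile)
  for (nm in names(images)) {
    s <- matrix(0, ntr, ntc)
    sums <- rowsum(images[[nm]][pure], tid)
    s[as.integer(rownames(sums))] <- sums
    ps <- box3(s)
    v <- ps / pooled_n
    v[pooled_n == 0] <- NA_real_
    out[[nm]] <- v
  }
  out
}

cell_pixels <- function(mask, label) {
  idx <- which(mask == label)
  if (length(idx) == 0L) stop("cell label not found in mask")
  cbind(row = ((idx - 1L) %% nrow(mask)) + 1L,
        col = ((idx - 1L) %/% nrow(mask)) + 1L)
}

#' Local-background-subtracted nuclear mean of one cell
#'
#' Expands the cell's nuclear mask by `local_bg_expand` microns, takes the
#' median of pixels inside the expansion but outside all nuclear masks as
#' the local background, and returns the background-subtracted mean nuclear
#' intensity, clipped at zero. Falls back to the global background (with a
#' warning) if no local non-masked pixel exists.
#'
#' @param image intensity matrix.
#' @param mask integer label matrix.
#' @param cell label of the cell.
#' @param params a [quant_params()] object.
#' @return scalar background-subtracted nuclear mean.
#' @export
local_background_subtract <- function(image, mask, cell, params = quant_params()) {
  px <- cell_pixels(mask, cell)
  r <- round(params$local_bg_expand / params$pixel_size)
  rows <- max(1L, min(px[, 1]) - r):min(nrow(mask), max(px[, 1]) + r)
  cols <- max(1L, min(px[, 2]) - r):min(ncol(mask), max(px[, 2]) + r)
  d <- crop_cheb_dist(rows, cols, px[, 1], px[, 2])
  sub_mask <- mask[rows, cols]
  sel <- d <= r & sub_mask == 0L
  nuc_mean <- mean(image[px])
  if (!any(sel)) {
    warning("no local non-masked pixels; falling back to global background")
    bg <- global_background(image, mask, params)
  } else {
    bg <- stats::median(image[rows, cols][sel])
  }
  max(0, nuc_mean - bg)
}

#' Cytoplasmic ring statistic of one cell
#'
#' The ring is the nuclear mask dilated by `ring_inner_offset + ring_width`
#' minus the mask dilated by `ring_inner_offset`, excluding pixels of (or
#' within the inner offset of) other nuclei. Returns the mean of the
#' brightest `ring_percentile` fraction of ring pixels minus the global
#' background, clipped at zero.
#'
#' @inheritParams local_background_subtract
#' @param global_bg precomputed [global_background()]; computed if `NULL`.
#' @return scalar ring statistic, or `NA` (with attribute `flag`) when the
#'   ring is empty due to crowding.
#' @export
cytoplasmic_ring_mean <- function(image, mask, cell, params = quant_params(),
                                  global_bg = NULL) {
  px <- cell_pixels(mask, cell)
  outer_r <- params$ring_inner_offset + params$ring_width
  rows <- max(1L, min(px[, 1]) - outer_r):min(nrow(mask), max(px[, 1]) + outer_r)
  cols <- max(1L, min(px[, 2]) - outer_r):min(ncol(mask), max(px[, 2]) + outer_r)
  d_self <- crop_cheb_dist(rows, cols, px[, 1], px[, 2])
  sub <- mask[rows, cols]
  other <- sub != 0L & sub != cell
  ring <- d_self > params$ring_inner_offset & d_self <= outer_r & sub == 0L
  if (any(other)) {
    opx <- which(other, arr.ind = TRUE)
    d_other <- crop_cheb_dist(rows, cols, rows[opx[, 1]], cols[opx[, 2]])
    ring <- ring & d_other > params$ring_inner_offset
  }
  if (!any(ring)) {
    out <- NA_real_
    attr(out, "flag") <- "ring_empty"
    return(out)
  }
  if (is.null(global_bg)) global_bg <- global_background(image, mask, params)
  max(0, top_fraction_mean(image[rows, cols][ring], params$ring_percentile) - global_bg)
}

#' CDK2 activity of one cell
#'
#' Ratio of the cytoplasmic ring statistic to the background-subtracted
#' nuclear mean of the sensor channel. The activity is marked missing when
#' the nuclear mean falls below `nuclear_floor` (guarding the ratio against
#' division blow-up) or when the ring is empty.
#'
#' @param sensor_image sensor-channel intensity matrix.
#' @inheritParams cytoplasmic_ring_mean
#' @return scalar activity ratio (>= 0), or `NA` with attribute `flag`.
#' @export
cdk2_activity <- function(sensor_image, mask, cell, params = quant_params(),
                          global_bg = NULL) {
  nuc <- local_background_subtract(sensor_image, mask, cell, params)
  if (nuc <= params$nuclear_floor) {
    out <- NA_real_; attr(out, "flag") <- "nuclear_floor"; return(out)
  }
  cyto <- cytoplasmic_ring_mean(sensor_image, mask, cell, params, global_bg)
  if (is.na(cyto)) return(cyto)
  cyto / nuc
}

#' Quantify every cell in one frame
#'
#' Vectorized per-frame measurement used by the pipeline: for each label it
#' reports the background-subtracted integrated H2B intensity, the sensor
#' nuclear mean, the cytoplasmic ring statistic and the CDK2 activity
#' ratio. Local backgrounds use the median of non-masked pixels in a square
#' window extending `local_bg_expand` microns beyond each nucleus; rings are
#' label-propagated Chebyshev annuli (identical geometry to the per-cell
#' operations).
#'
#' @param h2b_image,sensor_image intensity matrices.
#' @param mask integer label matrix.
#' @param params a [quant_params()] object.
#' @return data frame: label, row, col, area, total_h2b, nuclear_mean,
#'   cyto_mean, cdk2_activity, flag.
#' @export
quantify_frame <- function(h2b_image, sensor_image, mask,
                           params = quant_params()) {
  st <- attr(mask, "stats") %||% label_stats(mask)
  n <- nrow(st)
  empty <- data.frame(label = integer(0), row = numeric(0), col = numeric(0),
                      area = integer(0), total_h2b = numeric(0),
                      nuclear_mean = numeric(0), cyto_mean = numeric(0),
                      cdk2_activity = numeric(0), flag = character(0),
                      stringsAsFactors = FALSE)
  if (n == 0L) return(empty)
  # one distance transform per frame: chamfer distance of every background
  # pixel to the nearest nucleus, reused for the global background
  # exclusion, the perinuclear rings and the pure-background guard
  cap <- round(params$global_bg_dilate / params$pixel_size) + 2
  bg_dist <- chamfer_dist_cpp(mask, cap)
  gbg <- global_background(sensor_image, mask, params, bg_dist = bg_dist)

  inner <- params$ring_inner_offset
  outer_r <- inner + params$ring_width
  idx <- which(mask > 0L)
  lab_v <- mask[idx]
  h2b_sum <- as.numeric(rowsum(h2b_image[idx], lab_v))
  sen_sum <- as.numeric(rowsum(sensor_image[idx], lab_v))

  cyto <- ring_top_means(mask, bg_dist, sensor_image,
                         st$row, st$col, st$area,
                         inner, outer_r, params$ring_percentile)
  cyto <- pmax(0, cyto - gbg)

  # local background per cell: pooled mean of pure-background pixels
  # (beyond any perinuclear neighborhood) in coarse tiles spanning the
  # expansion window around each nucleus
  r <- round(params$local_bg_expand / params$pixel_size)
  guard <- outer_r + 4
  bgs <- tile_backgrounds(list(h2b = h2b_image, sen = sensor_image),
                          mask, bg_dist, guard, tile = max(16L, r))
  ti <- cbind(pmin(nrow(bgs$h2b), 1L + (round(st$row) - 1L) %/% bgs$tile),
              pmin(ncol(bgs$h2b), 1L + (round(st$col) - 1L) %/% bgs$tile))
  bg_h2b <- bgs$h2b[ti]
  bg_sen <- bgs$sen[ti]
  bg_h2b[is.na(bg_h2b)] <- stat_mode(h2b_image[bg_dist > guard])
  bg_sen[is.na(bg_sen)] <- gbg
  nuc_mean <- pmax(0, sen_sum / st$area - bg_sen)
  total_h2b <- pmax(0, h2b_sum - bg_h2b * st$area)
  act <- ifelse(nuc_mean > params$nuclear_floor, cyto / nuc_mean, NA_real_)
  flag <- rep("", n)
  flag[is.na(cyto)] <- "ring_empty"
  flag[nuc_mean <= params$nuclear_floor] <- "nuclear_floor"
  data.frame(label = st$label, row = st$row, col = st$col, area = st$area,
             total_h2b = total_h2b, nuclear_mean = nuc_mean,
             cyto_mean = cyto, cdk2_activity = act, flag = flag,
             stringsAsFactors = FALSE)
}
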