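#' Estimate the stage jitter between the last live frame and the IF image
#'
#' Exhaustive integer search: for every candidate shift in
#' `[-radius, radius]^2` the moving image is translated and the difference
#' score — mean absolute difference over the overlapping region — is
#' computed against the reference; the shift with the lowest score is the
#' jitter. Both images should be nuclear-channel images (H2B from the movie
#' versus Hoechst from the IF set).
#'
#' @param ref_image reference (last live-cell frame, nuclear channel).
#' @param moving_image image to align (fixed-cell nuclear stain).
#' @param search_radius maximum |shift| per axis, pixels.
#' @return list of class `jitter_shift`: `dy`, `dx` (the translation that
#'   was applied to the moving image) and `score` at the optimum.
#' @export
estimate_jitter <- function(ref_image, moving_image, search_radius = 20) {
  if (!all(dim(ref_image) == dim(moving_image))) {
    stop("images must have the same shape")
  }
  if (stats::sd(ref_image) < 1e-12 || stats::sd(moving_image) < 1e-12) {
    stop("degenerate input: image has zero variance")
  }
  nr <- nrow(ref_image); nc <- ncol(ref_image)
  best <- list(dy = 0L, dx = 0L, score = Inf)
  for (dy in -search_radius:search_radius) {
    r_ref <- max(1, 1 + dy):min(nr, nr + dy)
    r_mov <- r_ref - dy
    for (dx in -search_radius:search_radius) {
      c_ref <- max(1, 1 + dx):min(nc, nc + dx)
      c_mov <- c_ref - dx
      score <- mean(abs(ref_image[r_ref, c_ref] - moving_image[r_mov, c_mov]))
      if (score < best$score) best <- list(dy = dy, dx = dx, score = score)
    }
  }
  structure(list(dy = -best$dy, dx = -best$dx, score = best$score),
            class = "jitter_shift")
}

#' @export
print.jitter_shift <- function(x, ...) {
  cat(sprintf("jitter shift: dy=%d dx=%d (difference score %.4f)\n",
              x$dy, x$dx, x$score))
  invisible(x)
}

#' Match endpoint IF intensities to tracked cells
#'
#' Translates the IF images back by the estimated jitter and measures each
#' final-frame cell on each IF channel: background-subtracted nuclear mean
#' by default, or the cytoplasmic ring statistic for markers measured in
#' the cytoplasm (e.g. cytoplasmic Cyclin B1). Cells whose footprint leaves
#' the field after the shift are flagged missing rather than scored zero.
#'
#' @param final_mask label mask of the last live frame.
#' @param if_images named list of IF intensity matrices.
#' @param shift a `jitter_shift` (or integer `c(dy, dx)`) as applied to the
#'   IF images.
#' @param quant_params a [quant_params()] object.
#' @param cytoplasmic character vector of channel names measured on the
#'   ring instead of the nucleus.
#' @return data frame: label, one column per channel (`NA` when missing),
#'   and `edge_flag`.
#' @export
match_if_to_traces <- function(final_mask, if_images, shift,
                               quant_params = quant_params(),
                               cytoplasmic = cytoplasmic_markers()) {
  if (inherits(shift, "jitter_shift")) shift <- c(shift$dy, shift$dx)
  shift <- as.integer(shift)
  st <- attr(final_mask, "stats") %||% label_stats(final_mask)
  n <- nrow(st)
  out <- data.frame(label = st$label)
  nr <- nrow(final_mask); nc <- ncol(final_mask)
  # a cell is out of field if its (un)shifted centroid leaves the image
  edge <- st$row - shift[1] < 1 | st$row - shift[1] > nr |
    st$col - shift[2] < 1 | st$col - shift[2] > nc
  out$edge_flag <- edge
  for (ch in names(if_images)) {
    img <- shift_matrix(if_images[[ch]], -shift[1], -shift[2], fill = NA)
    # fill NA border with the channel median so background stats stay sane
    img[is.na(img)] <- stats::median(if_images[[ch]])
    gbg <- global_background(img, final_mask, quant_params)
    vals <- rep(NA_real_, n)
    for (l in st$label) {
      if (edge[match(l, st$label)]) next
      vals[match(l, st$label)] <- if (ch %in% cytoplasmic) {
        cytoplasmic_ring_mean(img, final_mask, l, quant_params, global_bg = gbg)
      } else {
        local_background_subtract(img, final_mask, l, quant_params)
      }
    }
    out[[ch]] <- vals
  }
  out
}
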