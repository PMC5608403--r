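# Internal image / numeric helpers shared across modules.

#' @import EBImage
NULL

# Shift a matrix by (dy, dx) filling vacated cells with `fill`.
shift_matrix <- function(m, dy, dx, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  src_r <- max(1, 1 - dy):min(nr, nr - dy)
  src_c <- max(1, 1 - dx):min(nc, nc - dx)
  if (length(src_r) == 0 || length(src_c) == 0) return(out)
  out[src_r + dy, src_c + dx] <- m[src_r, src_c]
  out
}

# One 3x3 grayscale max-dilation step (Chebyshev ball of radius 1).
max_dilate1 <- function(m) {
  out <- m
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    out <- pmax(out, shift_matrix(m, dy, dx, fill = -Inf))
  }
  out[!is.finite(out)] <- 0
  out
}

# Binary dilation by `k` Chebyshev steps (8-neighbor OR).
bin_dilate <- function(m, k) {
  for (i in seq_len(k)) {
    out <- m
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      out <- out | shift_matrix(m, dy, dx, fill = FALSE)
    }
    m <- out
  }
  m
}

# Propagate integer labels outward by `k` Chebyshev steps; contested pixels
# take the larger label (used only for perinuclear rings, where the small
# bias of the tie-break is immaterial).
propagate_labels <- function(lab, k) {
  d <- lab
  for (i in seq_len(k)) d <- max_dilate1(d)
  d
}

# 8-connected labeling (two-pass union-find; EBImage::bwlabel is
# 4-connected, so it is not used here).
label8 <- function(bw) {
  label8_cpp(matrix(as.logical(bw), nrow(bw), ncol(bw)))
}

# Relabel a label image so labels are contiguous 1..K (order preserved).
compact_labels <- function(lab) {
  u <- sort(unique(lab[lab > 0L]))
  if (length(u) == 0L) return(lab)
  out <- lab
  out[out > 0L] <- match(out[out > 0L], u)
  out
}

# Otsu threshold on a numeric vector (256-bin histogram).
otsu_threshold <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  r <- range(x)
  if (diff(r) <= 0) return(r[1])
  h <- tabulate(pmin(nbins, 1L + floor((x - r[1]) / diff(r) * nbins)), nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- r[1] + (seq_len(nbins) - 0.5) / nbins * diff(r)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  sb2 <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb2[!is.finite(sb2)] <- 0
  mids[which.max(sb2)]
}

# Laplacian-of-Gaussian kernel (rotationally symmetric), zero-sum normalized.
log_kernel <- function(sigma) {
  h <- max(2L, ceiling(3 * sigma))
  g <- expand.grid(x = -h:h, y = -h:h)
  r2 <- g$x^2 + g$y^2
  k <- (r2 - 2 * sigma^2) / sigma^4 * exp(-r2 / (2 * sigma^2))
  k <- k - mean(k)
  matrix(k, 2 * h + 1, 2 * h + 1)
}

# LoG response via separable passes: LoG = G''(x)G(y) + G(x)G''(y).
# Sign-flipped so bright blobs give positive responses.
log_response <- function(img, sigma) {
  h <- max(2L, ceiling(3 * sigma))
  x <- -h:h
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  gpp <- (x^2 - sigma^2) / sigma^4 * exp(-x^2 / (2 * sigma^2))
  gpp <- gpp - mean(gpp)   # zero response on constant images
  log_response_cpp(img, g, gpp)
}

# Per-label pixel statistics from a label image and an intensity image.
label_stats <- function(lab, img = NULL) {
  n <- max(lab)
  if (n == 0L) {
    return(data.frame(label = integer(0), area = integer(0),
                      row = numeric(0), col = numeric(0),
                      total = numeric(0), mean = numeric(0)))
  }
  idx <- which(lab > 0L)
  l <- lab[idx]
  area <- tabulate(l, n)
  rows <- ((idx - 1L) %% nrow(lab)) + 1L
  cols <- ((idx - 1L) %/% nrow(lab)) + 1L
  cr <- as.numeric(rowsum(rows, l)) / area
  cc <- as.numeric(rowsum(cols, l)) / area
  if (is.null(img)) {
    tot <- rep(NA_real_, n)
  } else {
    tot <- as.numeric(rowsum(img[idx], l))
  }
  data.frame(label = seq_len(n), area = area, row = cr, col = cc,
             total = tot, mean = tot / area)
}

# Pixels (row, col) of the digital segment between two points, thickened to
# all pixels within `width` of the continuous segment.
segment_pixels <- function(p1, p2, shape, width = 1.0) {
  lo <- pmax(1, floor(pmin(p1, p2)) - ceiling(width))
  hi <- pmin(shape, ceiling(pmax(p1, p2)) + ceiling(width))
  g <- expand.grid(row = lo[1]:hi[1], col = lo[2]:hi[2])
  v <- p2 - p1
  L2 <- sum(v^2)
  if (L2 == 0) {
    d2 <- (g$row - p1[1])^2 + (g$col - p1[2])^2
  } else {
    t <- pmin(1, pmax(0, ((g$row - p1[1]) * v[1] + (g$col - p1[2]) * v[2]) / L2))
    d2 <- (g$row - p1[1] - t * v[1])^2 + (g$col - p1[2] - t * v[2])^2
  }
  as.matrix(g[d2 <= width^2, , drop = FALSE])
}

# Locations of local maxima of a stats::density fit, tallest first.
density_peaks <- function(d, min_height_frac = 0.05) {
  y <- d$y; n <- length(y)
  i <- which(y > c(-Inf, y[-n]) & y >= c(y[-1], -Inf))
  i <- i[y[i] >= min_height_frac * max(y)]
  i[order(y[i], decreasing = TRUE)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so derived-seed draws do not perturb the main stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
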