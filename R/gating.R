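# Snapshot-mode cell-cycle phase gating from multiplexed IF marker tables:
# DNA content x EdU defines G0/G1, early S, S, late S and G2/M boxes;
# bimodal phospho-Rb splits G0 from G1 and phospho-histone H3 splits M from
# G2. Gates are fitted from the data (density valleys and DNA peak
# windows), with manual override through the returned gate object.

#' Normalize DNA content so the 2N peak sits at 1.0
#'
#' Divides by the location of the first major mode of the intensity
#' density, putting 2N cells near 1 and 4N cells near 2.
#'
#' @param dna positive DNA-content (integrated Hoechst) values; at least
#'   100 cells with a dominant 2N peak.
#' @param min_cells minimum number of cells required.
#' @return rescaled values, with the scale in attribute `"dna_2n"`.
#' @export
normalize_dna <- function(dna, min_cells = 100) {
  dna <- dna[is.finite(dna) & dna > 0]
  if (length(dna) < min_cells) {
    stop(sprintf("need >= %d cells to normalize DNA content", min_cells))
  }
  if (stats::sd(dna) < 1e-12) {
    # constant input: single trivial mode
    out <- dna / dna[1]
    attr(out, "dna_2n") <- dna[1]
    return(out)
  }
  d <- stats::density(dna, n = 1024)
  pk <- density_peaks(d, min_height_frac = 0.1)
  if (length(pk) == 0L) stop("no detectable DNA peak")
  # first major mode along the intensity axis (the 2N peak)
  scale <- d$x[min(pk)]
  if (scale <= 0) stop("no detectable DNA peak")
  out <- dna / scale
  attr(out, "dna_2n") <- scale
  out
}

#' Threshold between the two modes of a bimodal signal
#'
#' Fits a smoothed density to log-transformed values and places the
#' threshold at the density minimum between the two dominant modes (the
#' classic valley split for hypo- versus hyper-phosphorylated Rb).
#'
#' @param values positive intensities.
#' @param log_transform take log10 before fitting (default TRUE).
#' @param min_mode_frac a mode must reach this fraction of the tallest
#'   mode's density to count; guards against noise bumps.
#' @return threshold on the original scale.
#' @export
fit_bimodal_gate <- function(values, log_transform = TRUE,
                             min_mode_frac = 0.05) {
  v <- values[is.finite(values) & values > 0]
  x <- if (log_transform) log10(v) else v
  d <- stats::density(x, n = 1024)
  pk <- sort(density_peaks(d, min_height_frac = min_mode_frac))
  if (length(pk) < 2L) {
    stop("distribution is not bimodal; cannot place a gate")
  }
  # two dominant modes
  top2 <- sort(pk[order(d$y[pk], decreasing = TRUE)[1:2]])
  valley <- top2[1] + which.min(d$y[top2[1]:top2[2]]) - 1L
  thr <- d$x[valley]
  if (log_transform) 10^thr else thr
}

# Two thresholds splitting a trimodal (negative/intermediate/high) signal.
fit_trimodal_gates <- function(values, min_mode_frac = 0.05) {
  v <- values[is.finite(values) & values > 0]
  x <- log10(v)
  d <- stats::density(x, n = 1024)
  pk <- sort(density_peaks(d, min_height_frac = min_mode_frac))
  if (length(pk) < 3L) stop("expected a trimodal distribution")
  top3 <- sort(pk[order(d$y[pk], decreasing = TRUE)[1:3]])
  v1 <- top3[1] + which.min(d$y[top3[1]:top3[2]]) - 1L
  v2 <- top3[2] + which.min(d$y[top3[2]:top3[3]]) - 1L
  10^c(d$x[v1], d$x[v2])
}

#' Fit snapshot cell-cycle gates
#'
#' Normalizes DNA content, fits the EdU negative/intermediate/high
#' thresholds from the trimodal log-EdU density, the phospho-Rb threshold
#' from its bimodal density, and the pHH3 threshold likewise; DNA windows
#' default to `[0.8, 1.25]` (near 2N) and `[1.6, 2.5]` (near 4N) in
#' normalized units. Any fitted value can be overridden.
#'
#' @param records data frame with columns `dna`, `edu` and optionally
#'   `prb`, `phh3`.
#' @param overrides named list overriding fitted fields (`dna_2n_window`,
#'   `dna_4n_window`, `edu_neg_max`, `edu_high_min`, `prb_threshold`,
#'   `phh3_threshold`).
#' @return An object of class `gate_set`.
#' @export
fit_gates <- function(records, overrides = list()) {
  nd <- normalize_dna(records$dna)
  g <- list(dna_2n = attr(nd, "dna_2n"),
            dna_2n_window = c(0.8, 1.25),
            dna_4n_window = c(1.6, 2.5))
  edu_g <- fit_trimodal_gates(records$edu)
  g$edu_neg_max <- edu_g[1]; g$edu_high_min <- edu_g[2]
  g$prb_threshold <- if (!is.null(records$prb)) {
    fit_bimodal_gate(records$prb)
  } else NA_real_
  g$phh3_threshold <- if (!is.null(records$phh3)) {
    fit_bimodal_gate(records$phh3)
  } else NA_real_
  for (nm in names(overrides)) g[[nm]] <- overrides[[nm]]
  if (g$dna_2n_window[2] >= g$dna_4n_window[1]) {
    stop("dna_2n_window must lie below dna_4n_window")
  }
  if (g$edu_neg_max >= g$edu_high_min) {
    stop("edu_neg_max must be below edu_high_min")
  }
  class(g) <- "gate_set"
  g
}

#' @export
print.gate_set <- function(x, ...) {
  cat("Snapshot cell-cycle gates\n")
  cat(sprintf("  DNA 2N peak at %.1f; 2N window [%.2f, %.2f], 4N window [%.2f, %.2f]\n",
              x$dna_2n, x$dna_2n_window[1], x$dna_2n_window[2],
              x$dna_4n_window[1], x$dna_4n_window[2]))
  cat(sprintf("  EdU negative <= %.1f, high >= %.1f\n", x$edu_neg_max, x$edu_high_min))
  cat(sprintf("  phospho-Rb threshold %.1f, pHH3 threshold %.1f\n",
              x$prb_threshold, x$phh3_threshold))
  invisible(x)
}

#' Call cell-cycle phases from marker records
#'
#' Decision tree over conservative gates: EdU-negative cells with ~2N DNA
#' are G0 (hypo-phosphorylated Rb) or G1 (hyper-phosphorylated);
#' EdU-intermediate cells near 2N are early S and near 4N late S;
#' EdU-high cells are S; EdU-negative ~4N cells are M if pHH3-positive,
#' else G2. Records outside every box are `unassigned` (reported, never
#' dropped). Without `prb` the G0/G1 split is downgraded to a joint
#' `"G0/G1"` call; without `phh3`, `"G2/M"`.
#'
#' @param records data frame with `dna`, `edu`, optionally `prb`, `phh3`.
#' @param gates a [fit_gates()] result.
#' @return character vector of phase labels per record.
#' @export
call_phase <- function(records, gates) {
  nd <- records$dna / gates$dna_2n
  edu_cls <- ifelse(records$edu <= gates$edu_neg_max, "neg",
                    ifelse(records$edu >= gates$edu_high_min, "high", "mid"))
  in2n <- nd >= gates$dna_2n_window[1] & nd <= gates$dna_2n_window[2]
  in4n <- nd >= gates$dna_4n_window[1] & nd <= gates$dna_4n_window[2]
  n <- nrow(records)
  out <- rep("unassigned", n)
  has_prb <- !is.null(records$prb) && !is.na(gates$prb_threshold)
  has_phh3 <- !is.null(records$phh3) && !is.na(gates$phh3_threshold)
  sel <- edu_cls == "neg" & in2n
  out[sel] <- if (has_prb) {
    ifelse(records$prb[sel] < gates$prb_threshold, "G0", "G1")
  } else "G0/G1"
  out[edu_cls == "mid" & in2n] <- "earlyS"
  out[edu_cls == "high"] <- "S"
  out[edu_cls == "mid" & in4n] <- "lateS"
  sel <- edu_cls == "neg" & in4n
  out[sel] <- if (has_phh3) {
    ifelse(records$phh3[sel] >= gates$phh3_threshold, "M", "G2")
  } else "G2/M"
  out
}

#' Per-phase summaries of a protein of interest
#'
#' Probability densities of the protein per called phase plus per-phase
#' mean/sd/n of the protein and DNA content. Mitotic cells are flagged:
#' because of cell rounding, IF intensities are artificially inflated in M.
#'
#' @param records marker data frame including the `poi` column.
#' @param phases phase labels from [call_phase()].
#' @param poi column name of the protein of interest.
#' @return list of class `phase_summaries`: `densities` (named list of
#'   `stats::density` fits), `stats` (per-phase data frame with
#'   `mitotic_flag`), `unassigned_fraction`.
#' @export
phase_histograms <- function(records, phases, poi = "poi") {
  v <- records[[poi]]
  if (is.null(v)) stop("records lack protein-of-interest column: ", poi)
  lv <- intersect(c("G0", "G1", "earlyS", "S", "lateS", "G2", "M",
                    "G0/G1", "G2/M"), unique(phases))
  dens <- list(); st <- list()
  for (ph in lv) {
    x <- v[phases == ph & is.finite(v)]
    if (length(x) < 2L) {
      warning("phase ", ph, " has too few cells; omitted")
      next
    }
    dens[[ph]] <- stats::density(log10(pmax(x, .Machine$double.eps)))
    st[[ph]] <- data.frame(phase = ph, n = length(x), mean = mean(x),
                           sd = stats::sd(x),
                           dna_mean = mean(records$dna[phases == ph]),
                           mitotic_flag = ph %in% c("M", "G2/M"),
                           stringsAsFactors = FALSE)
  }
  out <- list(densities = dens, stats = do.call(rbind, st),
              unassigned_fraction = mean(phases == "unassigned"))
  class(out) <- "phase_summaries"
  out
}
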