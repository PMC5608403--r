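#' Parametric endpoint-IF protein profiles
#'
#' Expected endpoint immunofluorescence intensity (arbitrary units) for each
#' supported protein as a function of fate class and time since anaphase.
#' The shapes encode the qualitative single-cell dynamics of the core
#' cell-cycle machinery in cycling versus spontaneously quiescent cells:
#' Cyclin A2 rises linearly through S and G2 and is at baseline in
#' quiescent cells; Cyclin B1 rises supra-linearly from late S; Geminin
#' rises in S then plateaus; c-Myc and phospho-Rb climb through the cycle
#' and are off in quiescence; Cyclin D1 is U-shaped in cycling cells
#' (moderate G1, low S, moderate G2) but high and still rising in quiescent
#' cells; Cyclin E peaks at the G1/S boundary in cycling cells and rises
#' steadily in quiescent cells; p21 is low in cycling cells and accumulates
#' in quiescence; Cdt1 is high in G1, degraded in S, re-accumulates in G2,
#' and decays slowly in quiescence; EdU marks the S-phase window; p27 is a
#' flat control.
#'
#' @param s_window hours post-anaphase spanned by S phase in cycling cells.
#' @return A named list of functions `f(fate, tau)`; `tau` is hours since
#'   anaphase (vectorized). Each function returns intensities `>= 0`.
#' @export
protein_profiles <- function(s_window = c(5, 13)) {
  s0 <- s_window[1]; s1 <- s_window[2]
  base <- 50
  cyc <- function(f_cycling, quiescent_level) {
    # quiescent_level: function of tau for CDK2low-type cells
    function(fate, tau) {
      tau <- pmax(0, tau)
      v <- if (fate %in% c("CDK2inc", "CDK2emerge", "nondividing_emerge")) {
        f_cycling(tau)
      } else {
        quiescent_level(tau)
      }
      pmax(0, v)
    }
  }
  flat <- function(level) function(tau) rep(level, length(tau))
  list(
    CyclinA2 = cyc(function(t) base + 45 * pmax(0, t - s0), flat(base)),
    CyclinB1 = cyc(function(t) base + 6 * pmax(0, t - (s1 - 3))^2, flat(base)),
    Geminin = cyc(function(t) base + 400 * pmin(pmax(0, t - s0), 6) / 6,
                  flat(base)),
    cMyc = cyc(function(t) 120 + 30 * pmax(0, t - s0), flat(base)),
    phosphoRb = cyc(function(t) 300 + 25 * t, flat(base)),
    CyclinD1 = cyc(function(t) {
      v <- numeric(length(t))
      v[t < s0] <- 300
      mid <- t >= s0 & t < s1
      v[mid] <- pmax(120, 300 - 180 * (t[mid] - s0))
      v[t >= s1] <- pmin(300, 120 + 180 * (t[t >= s1] - s1))
      v
    }, function(t) 350 + 15 * t),
    CyclinE = cyc(function(t) {
      ifelse(t < s0, 100 + 60 * t, pmax(100, 100 + 60 * s0 - 80 * (t - s0)))
    }, function(t) 150 + 25 * t),
    p21 = cyc(function(t) rep(60, length(t)), function(t) 250 + 20 * t),
    Cdt1 = cyc(function(t) {
      v <- numeric(length(t))
      v[t < s0] <- 400
      mid <- t >= s0 & t < s1
      v[mid] <- pmax(80, 400 - 160 * (t[mid] - s0))
      v[t >= s1] <- pmin(400, 80 + 60 * (t[t >= s1] - s1))
      v
    }, function(t) pmax(120, 400 - 10 * t)),
    EdU = cyc(function(t) ifelse(t >= s0 & t <= s1, 600, 40), flat(40)),
    p27 = cyc(function(t) rep(200, length(t)), flat(200))
  )
}

# Markers measured in the cytoplasmic compartment (ring statistic) rather
# than the nucleus.
cytoplasmic_markers <- function() "CyclinB1"
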