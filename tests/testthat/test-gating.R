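test_that("DNA normalization puts the 2N peak at 1 and 4N near 2", {
  set.seed(1)
  pure2n <- 5000 * exp(stats::rnorm(500, 0, 0.05))
  nd <- normalize_dna(pure2n)
  d <- stats::density(nd)
  expect_lt(abs(d$x[which.max(d$y)] - 1), 0.05)

  mix <- c(5000 * exp(stats::rnorm(1500, 0, 0.05)),
           10000 * exp(stats::rnorm(500, 0, 0.05)))
  ndm <- normalize_dna(mix)
  dm <- stats::density(ndm, n = 1024)
  pk <- dm$x[cdk2map:::density_peaks(dm, 0.1)]
  expect_lt(abs(min(pk) - 1), 0.1)
  expect_lt(abs(max(pk) - 2), 0.1)

  cst <- normalize_dna(rep(4200, 200))
  expect_true(all(cst == 1))
  expect_error(normalize_dna(stats::runif(50)), "100 cells")
})

test_that("bimodal gates sit in the density valley between the modes", {
  set.seed(2)
  v <- 10^c(stats::rnorm(1000, 1, 0.1), stats::rnorm(1000, 3, 0.1))
  thr <- fit_bimodal_gate(v)
  expect_lt(abs(log10(thr) - 2), 0.2)
  # robust to asymmetric mixture weights
  for (w in c(0.2, 0.8)) {
    n1 <- round(2000 * w)
    vw <- 10^c(stats::rnorm(n1, 1, 0.1), stats::rnorm(2000 - n1, 3, 0.1))
    thrw <- fit_bimodal_gate(vw)
    expect_true(log10(thrw) > 1.3 && log10(thrw) < 2.7)
  }
  expect_error(fit_bimodal_gate(10^stats::rnorm(1000, 2, 0.1)),
               "not bimodal")
})

test_that("the phase decision tree reproduces the gating scheme", {
  set.seed(3)
  rec <- snapshot_population(n = 4000, seed = 3)
  gates <- fit_gates(rec)
  expect_lt(gates$dna_2n_window[2], gates$dna_4n_window[1])
  expect_lt(gates$edu_neg_max, gates$edu_high_min)

  mk <- function(dna, edu, prb = 1000, phh3 = 50) {
    data.frame(dna = dna, edu = edu, prb = prb, phh3 = phh3)
  }
  n2 <- gates$dna_2n
  expect_equal(call_phase(mk(n2, 30, prb = 100), gates), "G0")
  expect_equal(call_phase(mk(n2, 30, prb = 1000), gates), "G1")
  expect_equal(call_phase(mk(2 * n2, 30, phh3 = 2000), gates), "M")
  expect_equal(call_phase(mk(2 * n2, 30, phh3 = 50), gates), "G2")
  expect_equal(call_phase(mk(1.05 * n2, 300), gates), "earlyS")
  expect_equal(call_phase(mk(1.9 * n2, 300), gates), "lateS")
  expect_equal(call_phase(mk(n2, 3000), gates), "S")
  expect_equal(call_phase(mk(3 * n2, 30), gates), "unassigned")

  # missing markers downgrade resolution instead of guessing
  no_prb <- rec[, c("dna", "edu", "phh3")]
  g2 <- fit_gates(no_prb)
  ph2 <- call_phase(mk(n2, 30)[, c("dna", "edu")], g2)
  expect_equal(ph2, "G0/G1")
})

test_that("phase calls are deterministic and permutation-equivariant", {
  rec <- snapshot_population(n = 1000, seed = 8)
  gates <- fit_gates(rec)
  ph <- call_phase(rec, gates)
  perm <- sample(nrow(rec))
  expect_identical(call_phase(rec[perm, ], gates), ph[perm])
})

test_that("noiseless snapshots are gated with 100% accuracy, noisy >= 95%", {
  rec0 <- snapshot_population(n = 3000, noise_sdlog = 0, seed = 5)
  g0 <- fit_gates(rec0)
  ph0 <- call_phase(rec0, g0)
  expect_equal(mean(ph0 == rec0$true_phase), 1)

  rec <- snapshot_population(n = 3000, seed = 6)
  g <- fit_gates(rec)
  ph <- call_phase(rec, g)
  # conservative gates leave noise-displaced boundary cells unassigned;
  # accuracy is judged on the cells the gates commit to
  assigned <- ph != "unassigned"
  expect_gte(mean(ph[assigned] == rec$true_phase[assigned]), 0.95)
  expect_lt(mean(!assigned), 0.15)
  # conservative gating reports, never drops, the unassigned fraction
  hs <- phase_histograms(rec, ph)
  expect_equal(hs$unassigned_fraction, mean(ph == "unassigned"))
})

test_that("per-phase summaries expose the G0 versus G1 contrast", {
  rec <- snapshot_population(n = 4000, seed = 7)   # p21-like protein
  ph <- call_phase(rec, fit_gates(rec))
  hs <- phase_histograms(rec, ph)
  st <- hs$stats
  expect_gt(st$mean[st$phase == "G0"], 3 * st$mean[st$phase == "G1"])
  expect_true(st$mitotic_flag[st$phase == "M"])
  # noiseless means equal the generator's per-phase means
  rec0 <- snapshot_population(n = 3000, noise_sdlog = 0, seed = 5)
  ph0 <- call_phase(rec0, fit_gates(rec0))
  hs0 <- phase_histograms(rec0, ph0)
  expect_equal(hs0$stats$mean[hs0$stats$phase == "G0"], 600)
  expect_equal(hs0$stats$mean[hs0$stats$phase == "G1"], 80)
  # single-phase input yields one density
  occ <- stats::setNames(c(1, rep(0, 6)), c("G0", "G1", "earlyS", "S",
                                            "lateS", "G2", "M"))
  rec1 <- snapshot_population(300, occupancy = occ, seed = 2)
  hs1 <- suppressWarnings(phase_histograms(rec1, rec1$true_phase))
  expect_equal(names(hs1$densities), "G0")
})
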