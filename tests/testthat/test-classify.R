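cp <- classifier_params()
tgrid <- seq(0, 12, by = 0.2)

test_that("threshold rules reproduce the fate definitions", {
  expect_equal(classify_trace(rep(0.8, 61), tgrid, TRUE, cp), "CDK2inc")
  expect_equal(classify_trace(rep(0.3, 61), tgrid, TRUE, cp), "CDK2low")
  em <- ifelse(tgrid < 4, 0.3, pmin(2, 0.3 + 0.25 * (tgrid - 4)))
  expect_equal(classify_trace(em, tgrid, TRUE, cp), "CDK2emerge")
  # single dip below threshold at 1 h disqualifies under the strict rule
  dip <- rep(0.8, 61); dip[6] <- 0.49
  expect_equal(classify_trace(dip, tgrid, TRUE, cp), "unclassified")
  # ...but is forgiven with the 2-hour grace period variant
  expect_equal(classify_trace(dip, tgrid, TRUE,
                              classifier_params(grace_period = 2)), "CDK2inc")
  # nondividing cells
  t24 <- seq(0, 24, by = 0.2)
  expect_equal(classify_trace(rep(0.55, 121), t24, FALSE, cp),
               "prolonged_quiescent")
  nd <- ifelse(t24 < 10, 0.3, pmin(2, 0.3 + 0.3 * (t24 - 10)))
  expect_equal(classify_trace(nd, t24, FALSE, cp), "nondividing_emerge")
  # trace shorter than the rise confirmation window
  expect_equal(classify_trace(c(0.8, 0.8), c(0, 0.2), TRUE, cp), "unclassified")
})

test_that("classification equals a brute-force predicate oracle", {
  oracle <- function(a, tt, divided, p) {
    a_ok <- !is.na(a); a <- a[a_ok]; tt <- tt[a_ok]
    if (length(a) < p$rise_confirm) return("unclassified")
    run_ge <- function(x, thr, k) {
      n <- length(x)
      for (i in seq_len(n - k + 1)) {
        if (all(x[i:(i + k - 1)] >= thr)) return(TRUE)
      }
      FALSE
    }
    if (divided) {
      tau <- tt - tt[1]
      keep <- tau >= p$grace_period
      a <- a[keep]; tau <- tau[keep]
      if (length(a) < p$rise_confirm) return("unclassified")
      if (all(a >= p$inc_threshold)) return("CDK2inc")
      if (all(a < p$inc_threshold)) return("CDK2low")
      if (all(a[tau < p$emerge_min_low] < p$inc_threshold) &&
          run_ge(a, p$inc_threshold, p$rise_confirm)) return("CDK2emerge")
      return("unclassified")
    }
    if (run_ge(a, p$prolonged_threshold, p$rise_confirm)) {
      return("nondividing_emerge")
    }
    if (all(a < p$prolonged_threshold)) return("prolonged_quiescent")
    "unclassified"
  }
  set.seed(101)
  labels <- character(1000)
  for (k in 1:1000) {
    n <- sample(3:121, 1)
    tt <- seq(0, by = 0.2, length.out = n)
    kind <- sample(1:4, 1)
    a <- switch(kind,
                stats::runif(n, 0, 2),                      # unstructured
                rep(stats::runif(1, 0, 1), n) + stats::rnorm(n, 0, 0.1),
                ifelse(tt < stats::runif(1, 0, 10), 0.3,
                       0.3 + 0.25 * tt) + stats::rnorm(n, 0, 0.05),
                { x <- stats::runif(n, 0.4, 0.6); x[sample(n, 1)] <- NA; x })
    divided <- stats::runif(1) < 0.5
    got <- classify_trace(a, tt, divided, cp)
    labels[k] <- got
    expect_identical(got, oracle(a, tt, divided, cp))
  }
  # every trace received exactly one of the six labels
  expect_true(all(labels %in% c("CDK2inc", "CDK2low", "CDK2emerge",
                                "prolonged_quiescent", "nondividing_emerge",
                                "unclassified")))
})

test_that("R-point detection finds the activity buildup changepoint", {
  t24 <- seq(0, 24, by = 0.2)
  tr <- ifelse(t24 < 6, 0.3, 0.3 + 0.25 * (t24 - 6))
  rp <- detect_rpoint(tr, t24)
  expect_lt(abs(rp - 6), 0.41)                      # within 2 frames
  expect_true(is.na(detect_rpoint(rep(0.4, 121), t24)))
  # time-shift equivariance
  rp_shift <- detect_rpoint(tr, t24 + 3)
  expect_equal(rp_shift, rp + 3, tolerance = 1e-9)
})

test_that("R-point recovery on noisy emerging traces has sub-hour error", {
  t24 <- seq(0, 24, by = 0.2)
  errs <- vapply(1:50, function(s) {
    set.seed(s)
    t0 <- stats::runif(1, 4, 14)
    rate <- stats::runif(1, 0.2, 0.35)
    tr <- ifelse(t24 < t0, 0.3, pmin(2.2, 0.3 + rate * (t24 - t0))) +
      stats::rnorm(length(t24), 0, 0.05)
    detect_rpoint(tr, t24) - t0
  }, numeric(1))
  expect_lte(stats::median(abs(errs)), 0.8)
})

test_that("alignment puts the anchor at time zero and reconstructs IF times", {
  nl <- noiseless_fixture()
  ens <- suppressWarnings(align_ensemble(nl$analysis$traces, "anaphase",
                                         fates = nl$fates))
  # anchored lineages: minimum aligned time of the daughter segment is 0
  for (tid in unique(ens$anchors$track[!is.na(ens$anchors$anchor_time)])) {
    s <- ens$series[ens$series$track == tid, ]
    expect_true(any(abs(s$time) < 1e-9))
  }
  # IF x-coordinate equals movie length minus anaphase time, exactly
  a <- ens$anchors[!is.na(ens$anchors$anchor_time), ]
  cl <- nl$fates[match(a$track, nl$fates$track), ]
  truth_t <- nl$cohort$times[cl$last_anaphase_frame]
  expect_equal(a$if_time, 24 - truth_t, tolerance = 1e-9)
})

test_that("lineage fates recover the generator composition end to end", {
  e2e <- e2e_fixture()
  comp <- fate_composition(e2e$analysis$traces)
  tc <- true_composition(e2e$cohort)
  # pipeline fidelity: measured fractions match the cohort's true fates
  for (f in c("CDK2inc", "CDK2low", "CDK2emerge", "prolonged_quiescent",
              "nondividing_emerge", "divided")) {
    expect_lt(abs(comp[[f]] - tc[[f]]), 2.1)
  }
  expect_lt(comp[["unclassified"]], 2.1)
})
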